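test_that("scenario builders carry the printed couplings and timelines", {
  mad <- build_move_a_dot()
  expect_equal(mad$spec$n_memory, 3L)
  expect_equal(mad$spec$w1, 0.15)
  expect_equal(mad$spec$w2, 0.005)
  ev <- vapply(mad$events, `[[`, numeric(1), "time")
  expect_equal(sort(unique(ev)), c(1, 2, 3))
  expect_equal(mad$coincidence$threshold, 160)
  expect_equal(mad$coincidence$ramp_rate, 0.1)
  expect_equal(mad$coincidence$ramp_ceiling, 20)

  mt <- build_multi_task()
  expect_equal(mt$spec$n_memory, 4L)
  expect_equal(mt$spec$w1, 0.2)
  expect_equal(mt$spec$w2, 0.02)
  expect_equal(mt$events[[1]]$time, 0.5)

  ec <- build_error_correction()
  expect_equal(ec$spec$n_memory, 3L)
  expect_equal(ec$spec$w1, 0.2)
  expect_equal(ec$spec$w2, 0.02)
  kinds <- vapply(ec$events, `[[`, character(1), "kind")
  times <- vapply(ec$events, `[[`, numeric(1), "time")
  expect_equal(times[kinds == "central_off"], 3)
  expect_equal(times[kinds == "central_on"], 4)
  expect_gte(ec$duration, 7)
  # exactly one go signal in the manipulation scripts
  expect_equal(sum(vapply(mad$events, `[[`, character(1), "kind") == "go_signal"), 1L)
  expect_equal(sum(vapply(mt$events, `[[`, character(1), "kind") == "go_signal"), 1L)
})

test_that("task scripts validate their events", {
  spec <- network_spec(2, 0.1, 0.01)
  e1 <- task_event(1, "sensory_latch", 1)
  e2 <- task_event(0.5, "suppress", 2)
  expect_error(task_script(spec, list(e1, e2), duration = 4), "sorted")
  expect_error(task_script(spec, list(e1), duration = 0.5), "beyond")
  expect_error(task_event(-1, "sensory_latch", 1), "non-negative")
  expect_error(task_event(1, "explode", 1))
  bad <- task_script(spec, list(task_event(1, "sensory_latch", 9)), duration = 4)
  expect_error(run_task(bad, seed = 1), "Memory Unit index")
})

test_that("coincidence detection latches and ramps as specified", {
  cs <- coincidence_spec(c(1, 2), output_unit = 3)
  # below threshold, never crossed
  st <- coincidence_step(70, 80, cs, fired_at = NULL, t_ms = 10)
  expect_equal(st$current, 0)
  expect_null(st$fired_at)
  # crossing latches; ramp reaches 10 after 100 ms and caps at 20 by 200 ms
  st <- coincidence_step(90, 80, cs, fired_at = NULL, t_ms = 50)
  expect_equal(st$fired_at, 50)
  expect_equal(coincidence_step(0, 0, cs, fired_at = 50, t_ms = 150)$current, 10)
  expect_equal(coincidence_step(0, 0, cs, fired_at = 50, t_ms = 250)$current, 20)
  expect_equal(coincidence_step(0, 0, cs, fired_at = 50, t_ms = 2000)$current, 20)
  expect_error(coincidence_spec(c(1, 2), 3, threshold = 0), "positive")
})

test_that("move-a-dot binds position to motion and activates the output", {
  run <- run_task(build_move_a_dot(), seed = 1)
  sim <- run$result
  oc <- run$outcome
  expect_true(oc$output_activated)
  expect_gt(oc$activation_time, 2)       # not before the go signal
  # position/motion pair locks tightly before the 3 s suppression
  expect_lt(pair_error(sim, 1, 2, 2.5, 3), 0.01)
  # output unit quiet before the arrow appears, oscillating at the end
  pre <- sim$memory_E[sim$times < 1.9, 3]
  post <- sim$memory_E[sim$times > 3.5, 3]
  expect_lt(max(pre) - min(pre), 1)
  expect_gt(max(post) - min(post), 50)
  # suppressed units decay to quiet; output survives
  expect_identical(unname(oc$labels[1:2]), c("quiet", "quiet"))
  expect_match(oc$labels[3], "active")
})

test_that("a script without a go signal never engages the Central Unit", {
  mad <- build_move_a_dot()
  mad$events <- Filter(function(e) e$kind != "go_signal", mad$events)
  run <- run_task(mad, seed = 1)
  sim <- run$result
  expect_lt(max(sim$central_E), 1)
  expect_length(run$outcome$locked_pairs, 0)
  # no synchronizing force: the position/motion pair does not lock
  expect_gt(pair_error(sim, 1, 2, 2.3, 3), 0.01)
})

test_that("anti-phase pairs cannot drive the coincidence detector", {
  # in the multi-task final epoch the stored and output units are
  # anti-phase; their peaks never align, so the summed rate stays under the
  # 160 threshold even though each unit alone peaks near 85
  run <- run_task(build_multi_task(), seed = 2)
  sim <- run$result
  sel <- sim$times > 4
  s14 <- sim$memory_E[sel, 1] + sim$memory_E[sel, 4]
  expect_lt(max(s14), 160)
  expect_gt(max(sim$memory_E[sel, 1]), 70)
  expect_gt(max(sim$memory_E[sel, 4]), 70)
})

test_that("causality: no unit moves before its first event", {
  run <- run_task(build_move_a_dot(), seed = 5)
  sim <- run$result
  # first latch is at >= 1 s (jitter only delays); earlier samples are at
  # the decayed rest state
  expect_lt(max(sim$memory_E[sim$times < 1, ]), 0.2)
  expect_lt(max(sim$central_E[sim$times < 2]), 0.2)
})

test_that("every unit receives exactly one of the three memory-state labels", {
  for (seed in 1:3) {
    run <- run_task(build_multi_task(), seed = seed)
    labs <- run$outcome$labels
    expect_length(labs, 4)
    expect_true(all(labs %in% c("quiet", "active_synchronized",
                                "active_desynchronized")))
  }
})

test_that("multi-task stores the first dot and ends with anti-phase memories", {
  run <- run_task(build_multi_task(), seed = 2)
  sim <- run$result
  oc <- run$outcome
  # first-dot unit stays active after the 3 s suppression, manipulated units die
  expect_match(oc$labels[["first_dot"]], "active")
  expect_identical(unname(oc$labels[c("position", "motion")]),
                   c("quiet", "quiet"))
  expect_match(oc$labels[["output"]], "active")
  # stored memory and output are anti-phase in the final epoch
  err <- pair_error(sim, 1, 4, 4.3, 5)
  expect_lt(abs(err - 0.5), 0.1)
})

test_that("runs are reproducible per seed and differ across seeds", {
  r1 <- run_task(build_move_a_dot(), seed = 11)
  r2 <- run_task(build_move_a_dot(), seed = 11)
  r3 <- run_task(build_move_a_dot(), seed = 12)
  expect_identical(r1$result$memory_E, r2$result$memory_E)
  expect_gt(max(abs(r1$result$memory_E - r3$result$memory_E)), 1)
})

test_that("error correction reforms a lock after the reset", {
  run <- run_task(build_error_correction(), seed = 1)
  sim <- run$result
  # a position-motion pair is locked before shutdown
  pre <- locked_pair_label(sim, 2.4, 3)
  expect_true(pre %in% c("1-3", "2-3", "1-2"))
  # after reactivation some pair is locked again by the end
  post <- locked_pair_label(sim, 7.4, 8)
  expect_false(identical(post, "none"))
  # Central Unit silent during the shutdown window
  expect_lt(max(sim$central_E[sim$times > 3.5 & sim$times < 4]), 1)
})
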