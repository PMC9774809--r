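tl_from_labels <- function(labels, fps = 1) {
  fused_timeline(t(sapply(labels, delta_on)), fps = fps)
}

test_that("timelines are run-length encoded into contiguous maximal segments", {
  seg <- segments_from_timeline(tl_from_labels(c(1, 1, 2)))
  expect_equal(seg$phase_idx, c(1L, 2L))
  expect_equal(seg$start, c(0, 2))
  expect_equal(seg$end, c(2, 3))

  seg1 <- segments_from_timeline(tl_from_labels(rep(3, 10)))
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$end - seg1$start, 10)

  seg2 <- segments_from_timeline(tl_from_labels(c(1, 2, 1, 2), fps = 2))
  expect_equal(nrow(seg2), 4L)
  expect_equal(seg2$end - seg2$start, rep(0.5, 4))
  # total duration is n_frames / fps regardless of segmentation
  expect_equal(max(seg2$end), 4 / 2)
})

test_that("segment validation rejects gaps, inversions and split runs", {
  expect_error(phase_segments(data.frame(phase = "preparation",
                                         start = 1, end = 1)),
               "start >= end")
  expect_error(phase_segments(data.frame(
    phase = c("preparation", "clipping_cutting"),
    start = c(0, 11), end = c(10, 20))), "contiguous")
  expect_error(phase_segments(data.frame(
    phase = c("preparation", "preparation"),
    start = c(0, 10), end = c(10, 20))), "maximal")
})

test_that("metrics follow the worked occupancy/occurrence arithmetic", {
  seg <- phase_segments(data.frame(
    phase = c("preparation", "calot_triangle_dissection", "preparation"),
    start = c(0, 10, 25), end = c(10, 25, 30)))
  m <- compute_metrics(seg)
  expect_equal(m$total_time, 30)
  p1 <- m$per_phase[m$per_phase$phase == "preparation", ]
  expect_equal(p1$total_time, 15)
  expect_equal(p1$n_occurrences, 2L)
  expect_equal(p1$min_duration, 5)
  expect_equal(p1$max_duration, 10)
  expect_equal(p1$mean_duration, 7.5)
  expect_equal(p1$occupancy_pct, 50)
  p2 <- m$per_phase[m$per_phase$phase == "calot_triangle_dissection", ]
  expect_equal(p2$total_time, 15)
  expect_equal(p2$n_occurrences, 1L)
  # single occurrence: min = max = mean
  expect_equal(p2$min_duration, p2$max_duration)
  expect_equal(p2$mean_duration, 15)
  # absent phases report zeros
  p3 <- m$per_phase[m$per_phase$phase == "clipping_cutting", ]
  expect_equal(p3$n_occurrences, 0L)
  expect_equal(p3$total_time, 0)
  expect_equal(p3$occupancy_pct, 0)

  m1 <- compute_metrics(phase_segments(data.frame(
    phase = "clipping_cutting", start = 0, end = 60)))
  expect_equal(m1$per_phase$occupancy_pct[3], 100)
  expect_equal(sum(m1$per_phase$occupancy_pct[-3]), 0)
})

test_that("per-phase times and occupancies are conserved on random segments", {
  set.seed(101)
  for (rep in 1:25) {
    seg <- rand_segments(n_seg = sample(1:12, 1))
    m <- compute_metrics(seg)
    expect_equal(sum(m$per_phase$total_time), m$total_time,
                 tolerance = 1e-9)
    expect_equal(sum(m$per_phase$occupancy_pct), 100, tolerance = 1e-9)
  }
})

test_that("collapse_runs removes exactly the self-transitions", {
  expect_equal(collapse_runs(c(1, 1, 2, 2, 3)), c(1, 2, 3))
  expect_equal(collapse_runs(1), 1)
  expect_equal(collapse_runs(c(2, 2, 2)), 2)
  expect_equal(collapse_runs(c("a", "a", "b", "a")), c("a", "b", "a"))
  expect_error(collapse_runs(integer(0)), "empty")
})

test_that("transition estimation matches hand counts", {
  m <- estimate_transition_matrix(c(1, 2, 3))
  expect_equal(m$matrix[1, ], delta_on(2), ignore_attr = TRUE)
  expect_equal(m$matrix[2, ], delta_on(3), ignore_attr = TRUE)
  expect_true("clipping_cutting" %in% m$terminal_phases ||
                all(m$matrix[3, ] == 0))

  m2 <- estimate_transition_matrix(c(1, 2, 1, 2))
  expect_equal(m2$matrix[1, 2], 1)
  expect_equal(m2$matrix[2, 1], 1)

  m3 <- estimate_transition_matrix(list(c(1, 2), c(1, 3)))
  expect_equal(m3$matrix[1, 2:3], c(0.5, 0.5), ignore_attr = TRUE)

  expect_error(estimate_transition_matrix(c(1, 1, 2)), "collapse_runs")
})

test_that("pooled estimates equal independent tallies on random sequences", {
  set.seed(55)
  ps4 <- phase_set(letters[1:4])
  for (rep in 1:20) {
    seqs <- lapply(seq_len(sample(1:3, 1)), function(i) {
      len <- sample(2:20, 1)
      s <- integer(len); s[1] <- sample.int(4, 1)
      for (k in 2:len) s[k] <- sample(setdiff(1:4, s[k - 1]), 1)
      s
    })
    est <- estimate_transition_matrix(seqs, ps4)
    # independent tally via table() over pooled jump pairs
    from <- unlist(lapply(seqs, function(s) s[-length(s)]))
    to <- unlist(lapply(seqs, function(s) s[-1]))
    cnt <- unclass(table(factor(from, levels = 1:4),
                         factor(to, levels = 1:4)))
    want <- cnt / pmax(rowSums(cnt), 1)
    expect_equal(unname(est$matrix), unname(want), tolerance = 1e-12)
  }
})

test_that("per-sequence averaging differs from pooling as documented", {
  # seq1 gives a->b, seq2 gives a->c twice: pooling weights 1/3 vs 2/3,
  # averaging weights each procedure equally
  ps3 <- phase_set(c("a", "b", "c"))
  seqs <- list(c(1, 2), c(1, 3, 1, 3))
  pool <- estimate_transition_matrix(seqs, ps3, method = "pool")
  avg <- estimate_transition_matrix(seqs, ps3, method = "average")
  expect_equal(pool$matrix[1, 2:3], c(1, 2) / 3, ignore_attr = TRUE)
  expect_equal(avg$matrix[1, 2:3], c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("workflow model validation enforces the embedded-chain form", {
  m <- diag(7)[, c(2:7, 1)]          # cyclic permutation matrix, zero diag
  expect_s3_class(workflow_model(m), "workflow_model")
  expect_error(workflow_model(diag(7)), "self-transition forbidden")
  bad <- matrix(0, 7, 7); bad[1, 2] <- 0.5
  expect_error(workflow_model(bad), "sums to")
})

test_that("categorical Wasserstein follows the unit-gap CDF closed form", {
  expect_equal(wasserstein_categorical(delta_on(2, 4), delta_on(2, 4)), 0)
  expect_equal(wasserstein_categorical(delta_on(2, 4), delta_on(4, 4)), 2)
  expect_equal(wasserstein_categorical(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 1)
  expect_error(wasserstein_categorical(c(0.5, 0.5), c(1, 0, 0)),
               "different support sizes")
})

test_that("Wasserstein distance is a metric and matches the transport oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    p <- rand_probs(n); q <- rand_probs(n); r <- rand_probs(n)
    dpq <- wasserstein_categorical(p, q)
    expect_gte(dpq, 0)
    expect_equal(dpq, wasserstein_categorical(q, p), tolerance = 1e-12)
    expect_lte(dpq,
               wasserstein_categorical(p, r) +
                 wasserstein_categorical(r, q) + 1e-12)
    expect_equal(dpq, oracle_wasserstein(p, q), tolerance = 1e-9)
    expect_equal(wasserstein_categorical(p, p), 0)
  }
})

test_that("moving mass one index outward changes the distance by exactly eps", {
  ref <- c(0.6, 0.4, 0, 0, 0, 0, 0)
  stu <- c(0.6, 0.4, 0, 0, 0, 0, 0)
  eps <- 0.1
  stu2 <- stu; stu2[2] <- stu2[2] - eps; stu2[3] <- stu2[3] + eps
  expect_equal(wasserstein_categorical(ref, stu2),
               wasserstein_categorical(ref, stu) + eps)
})

test_that("workflow comparison excludes terminal rows and averages the rest", {
  set.seed(88)
  M <- default_lc_workflow()
  self <- compare_workflows(M, M)
  expect_true(all(self$per_phase_distance == 0))
  expect_equal(self$average_distance, 0)
  expect_equal(self$excluded_phases, "gallbladder_extraction")

  # single differing row: delta(p2) vs delta(p3) one index apart
  cyc <- matrix(0, 7, 7)
  for (i in 1:6) cyc[i, i + 1] <- 1
  cyc[7, 1] <- 1
  A <- workflow_model(cyc)
  b <- cyc; b[1, ] <- 0; b[1, 3] <- 1
  B <- workflow_model(b)
  cmp <- compare_workflows(A, B)
  expect_equal(unname(cmp$per_phase_distance["preparation"]), 1)
  expect_equal(sum(cmp$per_phase_distance), 1)
  expect_equal(cmp$average_distance, 1 / 7)

  # phase terminal in the student only is excluded
  s <- M$matrix; s[6, ] <- 0
  S <- workflow_model(s)
  cmp2 <- compare_workflows(M, S)
  expect_true("cleaning_coagulation" %in% cmp2$excluded_phases)
  expect_false("cleaning_coagulation" %in% names(cmp2$per_phase_distance))

  # nothing comparable -> error
  z <- matrix(0, 7, 7); z[1, 2] <- 1
  Z1 <- workflow_model(z)
  z2 <- matrix(0, 7, 7); z2[2, 3] <- 1
  Z2 <- workflow_model(z2)
  expect_error(compare_workflows(Z1, Z2), "no comparable rows")
})

test_that("evaluation metrics match the worked confusion arithmetic", {
  ev <- evaluate_predictions(c(1, 2, 2, 2), c(1, 1, 2, 2))
  expect_equal(ev$accuracy, 0.75)
  pc <- ev$per_class
  expect_equal(pc$recall, c(0.5, 1))
  expect_equal(pc$precision, c(1, 2 / 3))
  expect_equal(pc$f1, c(2 / 3, 0.8))
  expect_equal(pc$jaccard, c(0.5, 2 / 3))
  expect_equal(ev$f1, (2 / 3 + 0.8) / 2)
  expect_equal(ev$avg_error_per_phase_pct, 25)
  expect_equal(ev$avg_error_pct, 25)

  # perfect prediction
  ev1 <- evaluate_predictions(c(3, 3, 5), c(3, 3, 5))
  expect_equal(c(ev1$f1, ev1$precision, ev1$recall, ev1$accuracy,
                 ev1$jaccard), rep(1, 5))
  expect_equal(ev1$avg_error_pct, 0)
  expect_equal(ev1$avg_error_per_phase_pct, 0)

  # total failure: everything predicted as one wrong class
  ev0 <- evaluate_predictions(rep(2, 4), rep(1, 4))
  expect_equal(ev0$accuracy, 0)
  expect_equal(ev0$f1, 0)

  expect_error(evaluate_predictions(1:3, 1:4), "differ in length")
  expect_error(evaluate_predictions(integer(0), integer(0)), "empty")
})

test_that("confusion row sums equal per-class truth counts", {
  set.seed(99)
  truth <- sample.int(7, 200, replace = TRUE)
  pred <- sample.int(7, 200, replace = TRUE)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(factor(truth, levels = 1:7))))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 200)
})
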