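test_that("argmax labelling is deterministic with lowest-index tie-breaking", {
  expect_equal(argmax_label(c(0.1, 0.7, 0.2, 0, 0, 0, 0)), 2L)
  expect_equal(argmax_label(c(0.5, 0.5, 0, 0, 0, 0, 0)), 1L)
  expect_equal(argmax_label(rep(1 / 7, 7)), 1L)
  expect_error(argmax_label(numeric(0)), "empty")
})

test_that("pseudo-phase handling: elimination, renormalization, identity", {
  cfg <- fusion_config()
  expect_null(strip_pseudo(c(0.05, 0.05, 0, 0, 0, 0, 0, 0.9), cfg))
  expect_equal(strip_pseudo(c(0.5, 0.3, 0, 0, 0, 0, 0, 0.2), cfg),
               c(0.625, 0.375, 0, 0, 0, 0, 0))
  v <- c(0.4, 0.6, 0, 0, 0, 0, 0, 0)
  expect_equal(strip_pseudo(v, cfg), v[1:7])
  # under the renormalize policy nothing is ever eliminated
  cfg2 <- fusion_config(pseudo_policy = "renormalize")
  expect_equal(strip_pseudo(c(0.1, 0.1, 0, 0, 0, 0, 0, 0.8), cfg2),
               c(0.5, 0.5, 0, 0, 0, 0, 0))
  expect_error(strip_pseudo(c(0, 0, 0, 0, 0, 0, 0, 1), cfg2),
               "zero procedural mass")
})

test_that("synchronization follows the half-open interval convention", {
  v <- video_stream(matrix(1 / 7, 3, 7), fps = 2)   # frames at 0, 0.5, 1.0
  a <- audio_stream(0.4, 1.2, rbind(rand_probs(8)))
  sync <- synchronize(v, a)
  expect_equal(sync$windows[[1]]$frames, c(2L, 3L))
  expect_equal(sync$uncovered, 1L)

  # empty audio: all frames uncovered
  sync0 <- synchronize(v, audio_stream(numeric(0), numeric(0),
                                       matrix(numeric(0), 0, 8)))
  expect_length(sync0$windows, 0L)
  expect_equal(sync0$uncovered, 1:3)

  # a frame exactly at a fragment's end is NOT covered
  v1 <- video_stream(matrix(1 / 7, 3, 7), fps = 1)  # frames at 0, 1, 2
  a1 <- audio_stream(1, 2, rbind(rand_probs(8)))
  s1 <- synchronize(v1, a1)
  expect_equal(s1$windows[[1]]$frames, 2L)
  expect_true(3L %in% s1$uncovered)

  # a fragment covering no frames is returned with an empty index list
  a2 <- audio_stream(0.1, 0.4, rbind(rand_probs(8)))
  expect_length(synchronize(v1, a2)$windows[[1]]$frames, 0L)
})

test_that("window fusion is the stated weighted sum with split frame weights", {
  pad <- function(v) c(v, rep(0, 7 - length(v)))
  out <- fuse_window(pad(c(0.6, 0.4)),
                     rbind(pad(c(0.2, 0.8)), pad(c(0.4, 0.6))),
                     fusion_config())
  expect_equal(out, pad(c(0.45, 0.55)))
  # identical inputs are a fixed point
  d2 <- delta_on(2)
  expect_equal(fuse_window(d2, rbind(d2, d2), fusion_config()), d2)
  # one frame, disagreeing delta: 50/50 tie resolved to the lower index
  f <- fuse_window(delta_on(1), rbind(delta_on(2)), fusion_config())
  expect_equal(f, c(0.5, 0.5, 0, 0, 0, 0, 0))
  expect_equal(argmax_label(f), 1L)
  expect_error(fuse_window(delta_on(1), matrix(numeric(0), 0, 7),
                           fusion_config()),
               "covers no frames")
})

test_that("stream fusion composes coverage, elimination and fallback", {
  # worked 3-frame case: fragment [0.5, 2.5) of pure phase 3 over frames
  # t = 1, 2 that are pure phase 1 -> 0.5/0.5 tie, lowest index wins
  v <- video_stream(rbind(delta_on(1), delta_on(1), delta_on(1)), fps = 1)
  a <- audio_stream(0.5, 2.5, rbind(c(delta_on(3), 0)))
  tl <- fuse_streams(v, a)
  expect_equal(tl$labels, c(1L, 1L, 1L))
  expect_equal(as.character(tl$provenance),
               c("video_only", "fused", "fused"))
  expect_equal(tl$probs[2, ], c(0.5, 0, 0.5, 0, 0, 0, 0),
               ignore_attr = TRUE)

  # empty audio: every frame equals its video sample, provenance video_only
  set.seed(41)
  vr <- rand_video(12)
  tl0 <- fuse_streams(vr, audio_stream(numeric(0), numeric(0),
                                       matrix(numeric(0), 0, 8)))
  expect_equal(tl0$probs, vr$probs)
  expect_true(all(tl0$provenance == "video_only"))

  # all-pseudo audio: identical labels, provenance audio_eliminated under it
  ap <- audio_stream(0, 6, rbind(c(rep(0.1 / 7, 7), 0.9)))
  tlp <- fuse_streams(vr, ap)
  expect_equal(tlp$probs, vr$probs)
  expect_true(all(tlp$provenance[vr$timestamps < 6] == "audio_eliminated"))
  expect_true(all(tlp$provenance[vr$timestamps >= 6] == "video_only"))

  expect_error(fuse_streams(video_stream(matrix(numeric(0), 0, 7), fps = 1),
                            ap),
               "empty video stream")
  # sub-frame-period fragments are ignored with a warning
  expect_warning(fuse_streams(v, audio_stream(0.1, 0.4,
                                              rbind(c(delta_on(2), 0)))),
                 "cover no frame")
})

test_that("fused posteriors conserve probability mass", {
  set.seed(7)
  for (rep in 1:20) {
    v <- rand_video(n_frames = 15, fps = 2)
    a <- rand_audio(n_frag = 4, t_max = 7.5)
    tl <- fuse_streams(v, a)
    expect_equal(rowSums(tl$probs), rep(1, 15), tolerance = 1e-9)
  }
})

test_that("degenerate weights reduce fusion to a single modality", {
  set.seed(13)
  for (rep in 1:10) {
    v <- rand_video(n_frames = 20, fps = 2)
    a <- rand_audio(n_frag = 5, t_max = 10)
    video_labels <- apply(v$probs, 1L, argmax_label)

    tl0 <- fuse_streams(v, a, fusion_config(audio_weight = 0))
    expect_equal(tl0$labels, video_labels, ignore_attr = TRUE)

    tl1 <- fuse_streams(v, a, fusion_config(audio_weight = 1))
    sync <- synchronize(v, a)
    for (w in sync$windows) {
      if (!length(w$frames)) next
      frag <- strip_pseudo(a$probs[w$fragment, ], fusion_config())
      want <- if (is.null(frag)) video_labels[w$frames]
              else rep(argmax_label(frag), length(w$frames))
      expect_equal(tl1$labels[w$frames], want, ignore_attr = TRUE)
    }
  }
})

test_that("fusion is equivariant under phase permutations", {
  set.seed(29)
  for (rep in 1:5) {
    v <- rand_video(n_frames = 12, fps = 1)
    a <- rand_audio(n_frag = 3, t_max = 12)
    perm <- sample(7)
    # permuted phase set keeps argmax ties resolvable identically only for
    # tie-free inputs; random continuous vectors are tie-free a.s.
    psp <- phase_set(ps7$phases[perm])
    vp <- video_stream(v$probs[, perm], fps = 1, phase_set = psp)
    ap <- audio_stream(a$start, a$end, a$probs[, c(perm, 8L)],
                       phase_set = psp)
    tl <- fuse_streams(v, a)
    tlp <- fuse_streams(vp, ap)
    expect_equal(tlp$probs, tl$probs[, perm], ignore_attr = TRUE)
    expect_equal(perm[tlp$labels], tl$labels, ignore_attr = TRUE)
  }
})

test_that("each frame's output depends only on its own window", {
  set.seed(31)
  v <- rand_video(n_frames = 20, fps = 2)
  a <- rand_audio(n_frag = 5, t_max = 10)
  tl_full <- fuse_streams(v, a)
  sync <- synchronize(v, a)
  for (w in sync$windows) {
    if (!length(w$frames)) next
    alone <- audio_stream(a$start[w$fragment], a$end[w$fragment],
                          a$probs[w$fragment, , drop = FALSE])
    tl_one <- fuse_streams(v, alone)
    expect_equal(tl_one$probs[w$frames, ], tl_full$probs[w$frames, ])
    expect_equal(tl_one$labels[w$frames], tl_full$labels[w$frames])
  }
})
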