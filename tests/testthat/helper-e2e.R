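# Six-shot end-to-end run (2 behaviors x 3 shots), shared between the
# pipeline tests and the acceptance suite.

run_e2e <- function() {
  cached("e2e", {
    shots <- list()
    for (i in 1:3)
      shots[[i]] <- make_scene(list(list(bp_walk(), 30)),
                               image_size = c(96, 200), n_traj = 80,
                               seed = 100 + i)
    for (i in 1:3)
      shots[[3 + i]] <- make_scene(list(list(bp_head_turn(), 30)),
                                   image_size = c(96, 200), n_traj = 80,
                                   seed = 200 + i)
    for (i in seq_along(shots)) shots[[i]]$id <- paste0("shot", i)

    disc <- discover_behaviors(shots, k = 2, V = 50, seed = 1)
    true_labels <- vapply(seq_along(disc$intervals), function(i)
      interval_majority_label(disc$intervals[[i]],
                              shots[[disc$interval_shot[i]]]$labels),
      character(1))
    cmps <- extract_cluster_cmps(disc, shots, T = 10, top_k = 1,
                                 use_mbh = TRUE, mbh_V = 20, seed = 1)

    # align CMPs until one is correct (homography init, TTPS refinement)
    results <- list()
    for (cmp in cmps) {
      sp <- shots[[cmp$shot_p]]; sq <- shots[[cmp$shot_q]]
      hm <- align_cmp_homography(sp, sq, cmp, mode = "tm", use_fg = TRUE,
                                 seed = 1)
      al <- NULL
      if (!is.null(hm))
        al <- align_cmp_ttps(sp, sq, cmp, init_H = hm$H, max_points = 150,
                             seed = 1)
      ev <- evaluate_cmp(sp, sq, cmp, al %||% hm)
      results[[length(results) + 1L]] <- c(cmp, ev)
      if (isTRUE(ev$correct)) break
    }
    list(shots = shots, disc = disc, labels = true_labels, cmps = cmps,
         results = results)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
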