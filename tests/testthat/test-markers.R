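test_that("fold changes use pseudocounted ratios with symmetric flags", {
  v <- matrix(c(10, 3, 0, 10, 5, 3, 0, 4.5), nrow = 4,
              dimnames = list(c("G1", "G2", "G3", "G4"), c("e", "l")))
  m <- toy_averaged(v, days = c(0, 2), conditions = c("MEF", "DOXH"))
  fc <- fold_changes(m, list(c("e", "l")), theta = 2, pseudocount = 0.5)
  # the pseudocount pulls a nominal halving just inside the threshold:
  # 5.5/10.5 = 0.524 > 1/2, so no flag
  expect_equal(fc$ratio[fc$primary_id == "G1"], 5.5 / 10.5)
  expect_equal(fc$flag[fc$primary_id == "G1"], "none")
  expect_equal(fc$ratio[fc$primary_id == "G2"], 1)
  expect_equal(fc$flag[fc$primary_id == "G2"], "none")
  # double zero resolves to ratio 1 through the pseudocount
  expect_equal(fc$ratio[fc$primary_id == "G3"], 1)
  # 5/10.5 < 1/2: flagged down
  expect_equal(fc$flag[fc$primary_id == "G4"], "down")
  expect_error(fold_changes(m, list(c("e", "l")), theta = 1), "theta")
  expect_error(fold_changes(m, list(c("e", "zz"))), "zz")
})

test_that("down-up overlap matches hand-computed sets", {
  # 6 groups; late-up: G1..G4; early-down: G1, G2, G3, G6 -> 75%
  v <- matrix(c(
    10, 0.5, 5,    # G1: early 10 -> 0.5 (down), late 0.5 -> 5 (up)
    8, 1, 9,       # G2: down, up
    12, 2, 10,     # G3: down, up
    2, 2, 9,       # G4: none, up
    3, 3, 3,       # G5: none, none
    9, 1, 1        # G6: down, none
  ), nrow = 6, byrow = TRUE,
  dimnames = list(sprintf("G%d", 1:6), c("d0", "d2", "end")))
  m <- toy_averaged(v, days = c(0, 2, 30),
                    conditions = c("MEF", "DOXH", "iPSC"))
  expect_equal(down_up_overlap(m, c("d0", "d2"), c("d2", "end")), 75)

  # all late-up groups previously down -> 100; none down -> 0
  v2 <- v[c(1, 2, 3), ]
  m2 <- toy_averaged(v2, days = c(0, 2, 30),
                     conditions = c("MEF", "DOXH", "iPSC"))
  expect_equal(down_up_overlap(m2, c("d0", "d2"), c("d2", "end")), 100)
  v3 <- v[4, , drop = FALSE]
  m3 <- toy_averaged(v3, days = c(0, 2, 30),
                     conditions = c("MEF", "DOXH", "iPSC"))
  expect_equal(down_up_overlap(m3, c("d0", "d2"), c("d2", "end")), 0)

  # undefined when nothing is late-upregulated
  m4 <- toy_averaged(v[5, , drop = FALSE], days = c(0, 2, 30),
                     conditions = c("MEF", "DOXH", "iPSC"))
  expect_error(down_up_overlap(m4, c("d0", "d2"), c("d2", "end")),
               "undefined")
})

test_that("down-up overlap equals the brute-force set computation", {
  set.seed(91)
  for (i in 1:30) {
    v <- matrix(rpois(20 * 3, 4), nrow = 20,
                dimnames = list(sprintf("G%02d", 1:20),
                                c("d0", "d2", "end")))
    m <- toy_averaged(v, days = c(0, 2, 30),
                      conditions = c("MEF", "DOXH", "iPSC"))
    want <- tryCatch(oracle_overlap(v, c("d0", "d2"), c("d2", "end")),
                     error = function(e) NA)
    if (is.na(want)) {
      expect_error(down_up_overlap(m, c("d0", "d2"), c("d2", "end")))
    } else {
      expect_equal(down_up_overlap(m, c("d0", "d2"), c("d2", "end")), want)
    }
  }
})

test_that("category dispersion measures compositional stability", {
  ann <- c(G1 = "receptor", G2 = "receptor", G3 = "catalytic",
           G4 = "catalytic", G5 = "binding")
  # identical composition at both points -> zero dispersion
  v <- matrix(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), nrow = 5,
              dimnames = list(names(ann), c("t1", "t2")))
  m <- toy_averaged(v, days = c(0, 2), conditions = c("MEF", "DOXH"))
  disp <- category_dispersion(m, ann)
  expect_equal(disp$mean_sd, 0)
  expect_equal(unname(colSums(disp$percentages)), c(100, 100))

  # one category at 60% then 40% of detected groups: s.d. = 14.142...
  ann2 <- setNames(rep(c("x", "y"), each = 6),
                   c(paste0("x", 1:6), paste0("y", 1:6)))
  v2 <- cbind(t1 = c(rep(1, 6), 1, 1, 1, 1, 0, 0),  # 6x + 4y: x 60%
              t2 = c(1, 1, 1, 1, 0, 0, rep(1, 6)))  # 4x + 6y: x 40%
  rownames(v2) <- names(ann2)
  m2 <- toy_averaged(v2, days = c(0, 2), conditions = c("MEF", "DOXH"))
  d2 <- category_dispersion(m2, ann2)
  expect_equal(unname(d2$per_category_sd["x"]), sd(c(60, 40)))
  expect_equal(unname(d2$per_category_sd["x"]), 14.1421356, tolerance = 1e-6)

  # unannotated groups fall into "other"; single point warns, s.d. 0
  m1 <- toy_averaged(v2[, 1, drop = FALSE], days = 0, conditions = "MEF")
  expect_warning(d1 <- category_dispersion(m1, ann2["x1"]), "single")
  expect_equal(d1$mean_sd, 0)
  expect_true("other" %in% rownames(d1$percentages))
})

test_that("PCA reproduces geometry of the transformed data", {
  set.seed(5)
  v <- matrix(rpois(40 * 6, 8), nrow = 40,
              dimnames = list(sprintf("G%02d", 1:40),
                              sprintf("s%d", 1:6)))
  v[, 4] <- v[, 3]  # two identical samples
  m <- toy_averaged(v, days = c(0, 2, 5, 5, 8, 30),
                    conditions = c("MEF", rep("DOXH", 4), "ESC"))
  p <- run_pca(m)
  expect_equal(unname(p$scores["s3", ]), unname(p$scores["s4", ]))
  # scores preserve pairwise distances of the centred transformed data
  x <- t(log2(v + 1))
  x <- sweep(x, 2L, colMeans(x))
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(sum(p$variance_explained), 1)

  const <- toy_averaged(matrix(3, 4, 3, dimnames = list(letters[1:4],
                                                        c("a", "b", "c"))),
                        days = c(0, 2, 30),
                        conditions = c("MEF", "DOXH", "ESC"))
  expect_error(run_pca(const), "constant")
})

test_that("trajectory clustering recovers planted archetypes", {
  set.seed(13)
  cfg <- simulation_config(n_groups = 60,
                           archetype_mix = c(early_down = 1 / 3,
                                             fclass_up = 1 / 3,
                                             esc_like = 1 / 3,
                                             transient = 0, flat = 0),
                           mean_depth = 3000, marker_effect = 1, seed = 13)
  sim <- simulate_timecourse(cfg)
  av <- average_replicates(normalize_counts(simulate_counts(sim, cfg)))
  cl <- cluster_trajectories(av, K = 3, seed = 13)
  ari <- adjusted_rand(cl$cluster, sim$truth$archetype[names(cl$cluster)])
  expect_gte(ari, 0.9)

  expect_error(cluster_trajectories(av, K = 1), "at least 2")
  expect_error(cluster_trajectories(av, K = 61), "exceeds")

  # duplicated trajectories always share a cluster
  v <- av$values[1:10, ]
  v[2, ] <- v[1, ]
  m <- count_matrix(v, av$design, state = "averaged", mode = "rationale")
  cl2 <- cluster_trajectories(m, K = 3, seed = 1)
  expect_equal(unname(cl2$cluster[1L]), unname(cl2$cluster[2L]))
})

test_that("cluster selection demands a post-induction rise peaking at F-class", {
  pts <- c("MEF_d0", "DOXH_d2", "DOXH_d18", "DOXH_d30", "ESC_d30")
  days <- c(0, 2, 18, 30, 30)
  conds <- c("MEF", "DOXH", "DOXH", "DOXH", "ESC")
  v <- rbind(
    up_f1 = c(1, 3, 6, 9, 1), up_f2 = c(1, 2, 7, 10, 2),  # F-class up
    down1 = c(9, 6, 3, 1, 2), down2 = c(10, 5, 2, 1, 3),  # peak at day 0
    esc1 = c(1, 1, 2, 3, 9), esc2 = c(1, 2, 2, 3, 10)     # peak at ESC
  )
  colnames(v) <- pts
  m <- toy_averaged(v, days, conds)
  cl <- cluster_trajectories(m, K = 3, seed = 2)
  sel <- select_fclass_clusters(cl, m)
  expect_length(sel, 1L)
  expect_setequal(names(cl$cluster)[cl$cluster == sel], c("up_f1", "up_f2"))

  # a design with no DOXH arm has no resolvable F-class end state
  no_f <- toy_averaged(v[, c(1, 5)], days[c(1, 5)], conds[c(1, 5)])
  cl2 <- cluster_trajectories(no_f, K = 2, seed = 2)
  expect_error(select_fclass_clusters(cl2, no_f), "F-class")
})

test_that("marker ranking scores contributions on separating components", {
  pts <- c("MEF_d0", "DOXH_d18", "DOXH_d30", "ESC_d30")
  days <- c(0, 18, 30, 30)
  conds <- c("MEF", "DOXH", "DOXH", "ESC")
  set.seed(3)
  base <- matrix(rpois(40 * 4, 5), nrow = 40,
                 dimnames = list(sprintf("B%02d", 1:40), pts))
  mk <- rbind(MK1 = c(1, 30, 40, 1), MK2 = c(1, 30, 40, 1))
  v <- rbind(base, mk)
  m <- toy_averaged(v, days, conds)
  p <- run_pca(m)
  cl <- cluster_trajectories(m, K = 4, seed = 3)
  sel <- select_fclass_clusters(cl, m)
  r <- rank_markers(p, cl, sel)
  # identical trajectories score identically; ties break by id
  expect_equal(r$score[r$primary_id == "MK1"], r$score[r$primary_id == "MK2"])
  expect_lt(which(r$primary_id == "MK1"), which(r$primary_id == "MK2"))
  expect_true(all(r$score >= 0 & r$score <= 1))
  expect_true(all(diff(r$score) <= 0))
  expect_error(rank_markers(p, cl, sel,
                            state_labels = list(fclass = "DOXH_d30",
                                                esc = character(0),
                                                mef = "MEF_d0")),
               "no samples")
})

test_that("delta-delta-Ct fold changes follow the closed form", {
  ct <- data.frame(
    gene = "Cd24a", sample_id = c("cal", "s1", "s2"),
    ct_target = c(24, 23, 26), ct_reference = c(18, 18, 18),
    stringsAsFactors = FALSE)
  out <- relative_expression_ddct(ct, calibrator = "cal")
  expect_equal(out$fold_change[out$sample_id == "cal"], 1)   # self
  expect_equal(out$fold_change[out$sample_id == "s1"], 2)    # ddCt -1
  expect_equal(out$fold_change[out$sample_id == "s2"], 0.25) # ddCt +2
  expect_error(relative_expression_ddct(ct, calibrator = "zz"),
               "calibrator")
  ct$ct_reference[2] <- NA
  expect_error(relative_expression_ddct(ct, calibrator = "cal"), "reference")
})

test_that("hierarchical clustering orders leaves deterministically", {
  x <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), far = c(50, 50, 50),
             c = c(0.1, 0, 0))
  h <- hierarchical_cluster(x)
  expect_equal(h$height[1L], 0)  # identical rows merge at height 0
  expect_true(all(diff(h$height) >= 0))
  expect_equal(h$order[which(h$order == "a") + 1L], "b")  # duplicates adjacent
  # the outlier joins last
  expect_equal(h$merge[nrow(h$merge), 1L], -which(rownames(x) == "far"))
  expect_error(hierarchical_cluster(rbind(a = c(1, NaN), b = c(1, 2))),
               "NaN")
  expect_error(hierarchical_cluster(x[1, , drop = FALSE]), "2 rows")
})
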