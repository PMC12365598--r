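# Small maps built directly from hand-set or simulated bin states.

bc_map_from_sim <- function(n = 232, lens = c(Pp01 = 1e7, Pp02 = 1e7),
                            density = 15, morgans = 0.5, seed = 3,
                            error_rate = 0, missing_rate = 0) {
  cfg <- quick_config(n_progeny = n, chrom_lengths = lens,
    marker_density = density, map_length_morgans = morgans,
    error_rate = error_rate, missing_rate = missing_rate, seed = seed)
  tru <- simulate_progeny(simulate_parents(cfg))
  flt <- filter_genotypes(degrade_genotypes(tru))
  ob <- make_onebin(build_bins(phase_markers(flt$sets$sf_set)))
  list(map = build_map(ob, NULL, "BC"), truth = tru, cfg = cfg)
}

# Independent oracle: enumerate hidden flanking-state paths for the
# conditional class probabilities on a 3-bin toy.
oracle_bc_probs <- function(obs_l, obs_r, r1, r2) {
  p <- numeric(2)
  for (g in 0:1) {
    t1 <- if (is.na(obs_l)) 0.5 else {
      if (obs_l == g) 1 - r1 else r1
    }
    t2 <- if (is.na(obs_r)) 1 else {
      if (obs_r == g) 1 - r2 else r2
    }
    p[g + 1] <- t1 * t2
  }
  p / sum(p)
}

oracle_f2_probs_cond <- function(obs_l, obs_r, r1, r2) {
  ord <- expand.grid(u = 0:1, w = 0:1)
  p3 <- numeric(3)
  for (i in seq_len(4)) {
    u <- ord$u[i]
    w <- ord$w[i]
    lf <- 0
    for (j in seq_len(4)) {
      if (!is.na(obs_l) && ord$u[j] + ord$w[j] != obs_l) next
      tu <- if (ord$u[j] == u) 1 - r1 else r1
      tw <- if (ord$w[j] == w) 1 - r1 else r1
      lf <- lf + 0.25 * tu * tw
      if (is.na(obs_l)) {
        lf <- 0.25
        break
      }
    }
    rf <- 0
    for (j in seq_len(4)) {
      if (!is.na(obs_r) && ord$u[j] + ord$w[j] != obs_r) next
      tu <- if (ord$u[j] == u) 1 - r2 else r2
      tw <- if (ord$w[j] == w) 1 - r2 else r2
      rf <- rf + tu * tw
      if (is.na(obs_r)) {
        rf <- 1
        break
      }
    }
    p3[u + w + 1] <- p3[u + w + 1] + lf * rf
  }
  p3 / sum(p3)
}

toy_bc_map <- function() {
  states <- matrix(c(
    0L, 0L, 1L, 1L, NA,
    0L, 1L, NA, 1L, NA,
    0L, 1L, 0L, 1L, NA
  ), nrow = 3, byrow = TRUE,
  dimnames = list(NULL, sprintf("F1_%02d", 1:5)))
  ms <- toy_states(states, pos = c(1e6, 3e6, 6e6))
  build_map(ms, NULL, "BC")
}

test_that("QTL genotype probabilities match path enumeration on a toy", {
  mp <- toy_bc_map()
  cms <- mp$table$cm
  pos_q <- cms[1] + 0.4 * (cms[2] - cms[1])
  probs <- qtl_genotype_probs(mp, mp$table$group[1], pos_q)
  r1 <- kosambi_inv(pos_q - cms[1])
  r2 <- kosambi_inv(cms[2] - pos_q)
  r13 <- kosambi_inv(cms[3] - pos_q)
  for (v in 1:5) {
    sl <- mp$states[1, v]
    s2 <- mp$states[2, v]
    s3 <- mp$states[3, v]
    # nearest non-missing flanks
    obs_r <- if (!is.na(s2)) s2 else s3
    rr <- if (!is.na(s2)) r2 else r13
    expect_equal(unname(probs[v, ]),
      oracle_bc_probs(sl, obs_r, r1, rr), tolerance = 1e-9)
  }
  # at a non-missing marker the probabilities are an indicator
  at_mk <- qtl_genotype_probs(mp, mp$table$group[1], cms[2])
  expect_equal(unname(at_mk[1, ]), c(1, 0))
  expect_equal(unname(at_mk[2, ]), c(0, 1))
  # both flanks missing: prior
  expect_equal(unname(at_mk[5, ]), c(0.5, 0.5))
})

test_that("F2 genotype probabilities match ordered-state enumeration", {
  states <- matrix(c(
    "A", "H", "B", NA,
    "H", "H", "B", NA,
    "A", "B", "B", NA
  ), nrow = 3, byrow = TRUE,
  dimnames = list(NULL, sprintf("F1_%02d", 1:4)))
  ms <- toy_states(states, pos = c(1e6, 3e6, 6e6))
  mp <- build_map(ms, NULL, "F2")
  cms <- mp$table$cm
  pos_q <- cms[1] + 0.6 * (cms[2] - cms[1])
  probs <- qtl_genotype_probs(mp, mp$table$group[1], pos_q)
  r1 <- kosambi_inv(pos_q - cms[1])
  r2 <- kosambi_inv(cms[2] - pos_q)
  cls <- function(s) match(s, c("A", "H", "B")) - 1L
  for (v in 1:4) {
    expect_equal(unname(probs[v, ]),
      oracle_f2_probs_cond(cls(ms$states[1, v]), cls(ms$states[2, v]),
        r1, r2),
      tolerance = 1e-9)
  }
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
})

test_that("Haley-Knott at marker positions equals class-mean regression", {
  sim <- bc_map_from_sim(n = 120, lens = c(Pp01 = 8e6), seed = 13)
  mp <- sim$map
  set.seed(17)
  y <- rnorm(ncol(mp$states)) + mp$states[5, ]
  ph <- tibble::tibble(individual = colnames(mp$states), value = y)
  mk_cm <- mp$table$cm[5]
  probs <- qtl_genotype_probs(mp, mp$table$group[5], mk_cm)
  x <- probs[, "1"]
  fit_hk <- lm(y ~ x)
  fit_cm <- lm(y ~ factor(mp$states[5, ]))
  expect_equal(sum(resid(fit_hk)^2), sum(resid(fit_cm)^2),
    tolerance = 1e-9)
  # fitted class means agree
  mns <- tapply(fitted(fit_cm), mp$states[5, ], mean)
  expect_equal(unname(coef(fit_hk)[1]), unname(mns[["0"]]),
    tolerance = 1e-9)
  expect_equal(unname(coef(fit_hk)[1] + coef(fit_hk)[2]),
    unname(mns[["1"]]), tolerance = 1e-9)
})

test_that("a simulated BC QTL is recovered near its true position", {
  sim <- bc_map_from_sim(n = 232, seed = 3)
  qtl <- tibble::tibble(chrom = "Pp01", pos = 6e6, a = 1, d = 0, sd = 1)
  ph <- simulate_phenotypes(sim$truth, qtl, seed = 101)
  sc <- scan_interval_mapping(sim$map,
    dplyr::rename(ph, value = value))
  pk <- glance(sc)
  # QTL at 30 cM (6 Mb of a 50 cM / 10 Mb chromosome)
  expect_equal(pk$peak_group, "LG_Pp01")
  expect_lt(abs(pk$peak_cm - 30), 10)
  a_hat <- sc$profile$a[which.max(sc$profile$lod)]
  expect_lt(abs(abs(a_hat) - 1) / 1, 0.25)
  expect_true(all(sc$profile$lod >= 0))
  expect_true(all(sc$profile$pct_ev >= 0 & sc$profile$pct_ev <= 100))
})

test_that("an F2 scan with additive truth classifies as additive", {
  cfg <- quick_config(n_progeny = 400, chrom_lengths = c(Pp01 = 1e7),
    marker_density = 10, het_prob = c(1, 1), seed = 47)
  tru <- simulate_progeny(simulate_parents(cfg))
  flt <- filter_genotypes(degrade_genotypes(tru))
  ob <- make_onebin(build_bins(align_f2_labels(flt$sets$f2_set)))
  mp <- build_map(ob, NULL, "F2")
  qtl <- tibble::tibble(chrom = "Pp01", pos = 5e6, a = 1, d = 0, sd = 1)
  ph <- simulate_phenotypes(tru, qtl, seed = 103)
  sc <- scan_interval_mapping(mp, ph)
  pk <- sc$profile[which.max(sc$profile$lod), ]
  expect_lt(abs(pk$d / pk$a), 0.25)
  expect_equal(classify_gene_action(pk$a, pk$d), "A")
  # additive effect recovered with the (A - B)/2 sign convention
  expect_lt(abs(abs(pk$a) - 1), 0.35)
})

test_that("zero-variance phenotypes give a flagged flat profile", {
  mp <- toy_bc_map()
  ph <- tibble::tibble(individual = colnames(mp$states), value = 1)
  expect_warning(sc <- scan_interval_mapping(mp, ph), "variance")
  expect_true(all(sc$profile$lod == 0))
})

test_that("permutation thresholds are reproducible and quantile-correct", {
  sim <- bc_map_from_sim(n = 100, lens = c(Pp01 = 8e6), seed = 23)
  set.seed(29)
  ph <- tibble::tibble(individual = colnames(sim$map$states),
    value = rnorm(100))
  cfgp <- scan_config(n_permutations = 200, seed = 31)
  p1 <- permutation_threshold(sim$map, ph, cfgp)
  p2 <- permutation_threshold(sim$map, ph, cfgp)
  expect_identical(p1$max_lods, p2$max_lods)
  # alpha = 1 gives the minimum of the permutation maxima
  cfga <- scan_config(n_permutations = 200, alpha = 0.999, seed = 31)
  pa <- permutation_threshold(sim$map, ph, cfga)
  expect_equal(pa$threshold, min(pa$max_lods))
  expect_equal(p1$threshold,
    as.numeric(quantile(p1$max_lods, 0.95, type = 1)))
  expect_warning(scan_config(n_permutations = 50), "100 permutations")
})

test_that("support intervals drop one LOD and truncate at IBD", {
  # synthetic triangular profile: peak 5 at 30 cM, slope 0.5 / cM
  cm_grid <- seq(20, 40, by = 1)
  prof <- tibble::tibble(group = "LG_Pp01", pos_cm = cm_grid,
    lod = 5 - 0.5 * abs(cm_grid - 30), pct_ev = 10, a = 1, d = NA)
  mt <- tibble::tibble(group = "LG_Pp01", marker = paste0("Pp01_", cm_grid),
    chrom = "Pp01", pos = cm_grid * 2e5, n_markers = 1, cm = cm_grid)
  sc <- structure(list(profile = prof,
    map = list(table = mt, design = "BC"), n = 100), class = "qtl_scan")
  si <- lod_support_interval(sc, drop = 1)
  expect_equal(si$cm_lo, 28)
  expect_equal(si$cm_hi, 32)
  expect_false(si$open_ended)

  ibd <- tibble::tibble(chrom = "Pp01", start = 31 * 2e5, end = 40 * 2e5,
    length = 9 * 2e5)
  si2 <- lod_support_interval(sc, drop = 1, ibd = ibd)
  expect_equal(si2$bp_hi, 31 * 2e5)
  expect_true(si2$truncated_at_ibd)

  flat <- sc
  flat$profile$lod <- 3
  si3 <- lod_support_interval(flat, drop = 1)
  expect_true(si3$open_ended)
  expect_equal(si3$cm_lo, 20)
  expect_equal(si3$cm_hi, 40)
})

test_that("gene action classes follow the published bands", {
  expect_equal(classify_gene_action(-4.5, -1.2), "PD")
  expect_equal(classify_gene_action(2, 0), "A")
  expect_equal(classify_gene_action(1, 1), "D")
  expect_equal(classify_gene_action(1, 2), "OD")
  expect_equal(classify_gene_action(0, 1), "n/a")
  expect_equal(classify_gene_action(-20.9, 15.6), "PD") # table worked row
  # band edges go to the lower-dominance class
  expect_equal(classify_gene_action(1, 0.25), "A")
  expect_equal(classify_gene_action(1, 0.75), "PD")
  expect_equal(classify_gene_action(1, 1.25), "D")
  # scale invariance
  set.seed(83)
  for (k in 1:20) {
    a <- rnorm(1)
    d <- rnorm(1)
    s <- runif(1, 0.1, 10)
    expect_equal(classify_gene_action(a, d),
      classify_gene_action(s * a, s * d))
  }
})

test_that("segregation chi-square reproduces the worked examples", {
  t1 <- segregation_chi2(c(85, 91), c(1, 1))
  expect_equal(round(t1$chi2, 2), 0.20)
  expect_equal(t1$df, 1L)
  t2 <- segregation_chi2(c(80, 60), c(1, 1))
  expect_equal(round(t2$chi2, 2), 2.86)
  t3 <- segregation_chi2(c(88, 88), c(1, 1))
  expect_equal(t3$chi2, 0)
  t4 <- segregation_chi2(c(50, 110, 40), c(1, 2, 1))
  expect_equal(t4$df, 2L)
  expect_error(segregation_chi2(c(0, 0), c(1, 1)), "zero")
})

test_that("a binary trait maps to its co-segregating bin", {
  sim <- bc_map_from_sim(n = 100, lens = c(Pp01 = 8e6), seed = 37)
  ob <- marker_states(
    dplyr::select(sim$map$table, marker, chrom, pos, n_markers),
    sim$map$states
  )
  trait <- sim$map$states[7, ]
  names(trait) <- colnames(sim$map$states)
  hit <- map_major_gene(trait, ob)
  expect_equal(hit$bin, ob$markers$marker[7])
  expect_equal(hit$mismatch_rate, 0)
  expect_true(hit$linked)

  set.seed(41)
  noisy <- trait
  flip <- sample(length(noisy), 2)
  noisy[flip] <- 1L - noisy[flip]
  hit2 <- map_major_gene(noisy, ob)
  expect_equal(hit2$bin, ob$markers$marker[7])
  expect_lt(hit2$mismatch_rate, 0.05)

  rand <- setNames(rbinom(100, 1, 0.5), names(trait))
  hit3 <- map_major_gene(rand, ob)
  expect_false(hit3$linked)
  expect_error(map_major_gene(rep(1, 100), ob), "binary")
})

test_that("cross-map reporting follows the precedence rules", {
  res <- tibble::tibble(
    trait = c("MD", "MD", "FC", "SSC", "SSC"),
    year = c(21, 21, 21, 21, 22),
    map = c("SF", "SFxZP", "SFxZP", "ZP", "ZP"),
    region = c("LG4", "LG4", "LG5", "LG5", "LG5"),
    lod = c(4.0, 3.5, 4.2, 3.0, 3.1),
    threshold = c(2.5, 3.3, 3.3, 2.7, 2.7)
  )
  rep <- report_qtls(res)
  # MD LG4: significant in SF and SFxZP, SF has higher LOD
  md <- rep[rep$trait == "MD", ]
  expect_equal(md$map, "SF")
  # FC LG5: significant only in the combined map: excluded
  expect_false(any(rep$trait == "FC"))
  # SSC LG5 in both years: consistent
  ssc <- rep[rep$trait == "SSC", ]
  expect_equal(nrow(ssc), 2)
  expect_true(all(ssc$consistent))
  # nothing significant: empty report
  none <- dplyr::mutate(res, lod = 1)
  expect_equal(nrow(report_qtls(none)), 0)
})
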