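two_traits <- function(seed = 51, n_var = 30) {
  rec1 <- make_records(n_var, seed = seed)
  rec2 <- make_records(n_var, seed = seed + 1)
  rec2[c("chrom", "pos", "ref", "alt")] <- rec1[c("chrom", "pos", "ref", "alt")]
  list(ss1 = as_sumstats(rec1, trait_id = "t1"),
       ss2 = as_sumstats(rec2, trait_id = "t2"))
}

test_that("harmonisation keeps identical lists, flips swapped alleles, drops ambiguity", {
  tt <- two_traits()
  pairs <- harmonise_pair(tt$ss1, tt$ss2)
  expect_equal(nrow(pairs), 30)
  expect_equal(attr(pairs, "n_flipped"), 0L)
  expect_equal(pairs$beta2, tt$ss2$beta)

  # ref/alt swapped in the second file: betas negated, eaf complemented
  swapped <- as.data.frame(tt$ss2)
  names(swapped)[names(swapped) == "ref"] <- "tmp"
  names(swapped)[names(swapped) == "alt"] <- "ref"
  names(swapped)[names(swapped) == "tmp"] <- "alt"
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  pairs_sw <- harmonise_pair(tt$ss1, as_sumstats(swapped))
  expect_equal(pairs_sw$beta2, tt$ss2$beta)
  expect_equal(pairs_sw$eaf2, tt$ss2$eaf)
  expect_equal(abs(cor(pairs_sw$beta2, pairs$beta2)), 1)

  # strand-ambiguous A/T variant at eaf 0.5 is dropped and logged
  amb1 <- as.data.frame(tt$ss1)
  amb1$ref[3] <- "A"; amb1$alt[3] <- "T"; amb1$eaf[3] <- 0.5
  amb2 <- as.data.frame(tt$ss2)
  amb2$ref[3] <- "A"; amb2$alt[3] <- "T"
  pairs_amb <- harmonise_pair(as_sumstats(amb1), as_sumstats(amb2))
  expect_equal(nrow(pairs_amb), 29)
  lg <- attr(pairs_amb, "log")
  expect_equal(lg$removed[lg$event == "strand_ambiguous_dropped"], 1)

  expect_error(harmonise_pair(tt$ss1, tt$ss2,
                              region = list(chrom = "9", start = 1, end = 2)),
               class = "postgwas_empty_intersection")
})

test_that("log-space posteriors reproduce brute-force configuration enumeration", {
  brute_force_pp <- function(l1, l2, pr) {
    l <- length(l1)
    h <- c(1, pr$p1 * sum(exp(l1)), pr$p2 * sum(exp(l2)), 0,
           pr$p12 * sum(exp(l1 + l2)))
    for (j in seq_len(l)) for (k in seq_len(l)) {
      if (j != k) h[4] <- h[4] + pr$p1 * pr$p2 * exp(l1[j] + l2[k])
    }
    h / sum(h)
  }
  set.seed(52)
  for (l in c(1, 2, 17, 50)) {
    tt <- two_traits(seed = 52 + l, n_var = max(l, 2))
    pairs <- harmonise_pair(tt$ss1, tt$ss2)[seq_len(l), ]
    pr <- coloc_priors()
    res <- coloc_posteriors(pairs, pr, omega1 = 0.0225, omega2 = 0.04)
    lam1 <- log_abf(pairs$beta1, pairs$se1^2, 0.0225)
    lam2 <- log_abf(pairs$beta2, pairs$se2^2, 0.04)
    expect_equal(unname(res$pp), brute_force_pp(lam1, lam2, pr), tolerance = 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-12)
  }
})

test_that("the large-region log-subtraction path agrees with enumeration", {
  tt <- two_traits(seed = 53, n_var = 250)
  pairs <- harmonise_pair(tt$ss1, tt$ss2)
  res_big <- coloc_posteriors(pairs, omega1 = 0.0225, omega2 = 0.0225)
  # force the direct-enumeration branch by splitting: recompute S3 by hand
  lam1 <- log_abf(pairs$beta1, pairs$se1^2, 0.0225)
  lam2 <- log_abf(pairs$beta2, pairs$se2^2, 0.0225)
  grid <- outer(lam1, lam2, "+"); diag(grid) <- -Inf
  m <- max(grid); s3_direct <- m + log(sum(exp(grid - m)))
  pr <- coloc_priors()
  logh <- c(0, log(pr$p1) + max(lam1) + log(sum(exp(lam1 - max(lam1)))),
            log(pr$p2) + max(lam2) + log(sum(exp(lam2 - max(lam2)))),
            log(pr$p1) + log(pr$p2) + s3_direct,
            log(pr$p12) + max(lam1 + lam2) + log(sum(exp(lam1 + lam2 - max(lam1 + lam2)))))
  pp_direct <- exp(logh - max(logh)) / sum(exp(logh - max(logh)))
  expect_equal(unname(res_big$pp), unname(pp_direct), tolerance = 1e-10)
})

test_that("posteriors are permutation-invariant and trait-symmetric", {
  tt <- two_traits(seed = 54, n_var = 40)
  pairs <- harmonise_pair(tt$ss1, tt$ss2)
  pr <- coloc_priors(p1 = 2e-4, p2 = 5e-5, p12 = 1e-5)
  res <- coloc_posteriors(pairs, pr, omega1 = 0.0225, omega2 = 0.04)

  perm <- pairs[sample(nrow(pairs)), ]
  res_p <- coloc_posteriors(perm, pr, omega1 = 0.0225, omega2 = 0.04)
  expect_equal(res_p$pp, res$pp, tolerance = 1e-12)

  swapped <- pairs
  names(swapped) <- sub("1$", "x", names(swapped))
  names(swapped) <- sub("2$", "1", names(swapped))
  names(swapped) <- sub("x$", "2", names(swapped))
  res_s <- coloc_posteriors(swapped[names(pairs)],
                            coloc_priors(p1 = 5e-5, p2 = 2e-4, p12 = 1e-5),
                            omega1 = 0.04, omega2 = 0.0225)
  expect_equal(res_s$pp[["PP1"]], res$pp[["PP2"]], tolerance = 1e-12)
  expect_equal(res_s$pp[["PP2"]], res$pp[["PP1"]], tolerance = 1e-12)
  expect_equal(res_s$pp[["PP0"]], res$pp[["PP0"]], tolerance = 1e-12)
  expect_equal(res_s$pp[["PP3"]], res$pp[["PP3"]], tolerance = 1e-12)
  expect_equal(res_s$pp[["PP4"]], res$pp[["PP4"]], tolerance = 1e-12)
})

test_that("flat data favour the null with default priors", {
  n_var <- 100
  rec <- make_records(n_var, seed = 55)
  rec$beta <- rep(0, n_var)
  rec$se <- rep(0.5, n_var)  # large V: Bayes factors are pure Occam penalties
  rec$p <- rep(1, n_var)
  tt2 <- rec; tt2$beta <- rep(0, n_var)
  pairs <- harmonise_pair(as_sumstats(rec), as_sumstats(tt2))
  res <- coloc_posteriors(pairs, omega1 = 0.0225, omega2 = 0.0225)
  expect_gt(res$pp[["PP0"]], 0.9)
  expect_equal(res$decision, "inconclusive")
})

test_that("the strong-colocalisation decision rule follows the sum and ratio gates", {
  as_res <- function(pp) structure(list(pp = setNames(pp, paste0("PP", 0:4))),
                                   class = "coloc_result")
  expect_equal(coloc_decision(as_res(c(0.002, 0.001, 0.001, 0.001, 0.995))), "strong_coloc")
  expect_equal(coloc_decision(as_res(c(0.005, 0.0025, 0.0025, 0.2, 0.79))), "inconclusive")
  expect_equal(coloc_decision(as_res(c(0.02, 0.015, 0.015, 0.05, 0.90))), "inconclusive")
  expect_equal(coloc_decision(as_res(c(0, 0, 0, 0, 1))), "strong_coloc")  # PP3 = 0
  expect_equal(coloc_decision(as_res(c(0, 0, 0, 0.995, 0.005))), "distinct")
})

test_that("paired-study truth records round-trip and match the coloc outcome", {
  cfg <- sim_config(5000, 200, blocks = data.frame(length = rep(50, 4), rho = 0.9),
                    seed = 56)
  pair <- make_paired_studies(cfg, mode = "shared", ve = 0.05)
  expect_equal(pair$truth$mode, "shared")
  expect_equal(pair$truth$causal1, pair$truth$causal2)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(pair$truth, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$causal1, pair$truth$causal1)

  res <- coloc_posteriors(harmonise_pair(pair$ss1, pair$ss2))
  expect_gt(res$pp[["PP4"]], 0.9)
  expect_equal(res$decision, "strong_coloc")
  expect_equal(glance(res)$decision, "strong_coloc")
  expect_equal(sum(tidy(res)$posterior), 1, tolerance = 1e-12)
})
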