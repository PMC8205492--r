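spike_ss <- function(spikes, n = 200, seed = 31, spacing = 10000) {
  rec <- make_records(n, seed = seed, spacing = spacing)
  rec$p <- pmax(rec$p, 0.5)  # background clearly null
  rec$beta <- qnorm(rec$p / 2, lower.tail = FALSE) * rec$se
  for (k in seq_len(nrow(spikes))) {
    i <- spikes$row[k]
    rec$p[i] <- spikes$p[k]
    rec$beta[i] <- qnorm(spikes$p[k] / 2, lower.tail = FALSE) * rec$se[i]
  }
  as_sumstats(rec)
}

test_that("find_loci returns nothing when no variant passes", {
  ss <- spike_ss(data.frame(row = integer(), p = numeric()))
  expect_equal(nrow(find_loci(ss, 4.54e-9)), 0)
})

test_that("a single spike produces one locus centred on it", {
  ss <- spike_ss(data.frame(row = 100, p = 1e-12))
  loci <- find_loci(ss, 4.54e-9, flank_bp = 500000)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$index_pos, ss$pos[100])
  expect_lte(loci$end - loci$start + 1, 1000001)
  expect_true(all(abs(ss$pos[loci$members[[1]]] - loci$index_pos) <= 500000))
})

test_that("locus windows merge like an interval oracle", {
  # spikes 400 kb apart: windows overlap -> one locus keeping the smaller p
  ss <- spike_ss(data.frame(row = c(100, 140), p = c(1e-12, 1e-10)))
  loci <- find_loci(ss, 4.54e-9)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$index_p, 1e-12)

  # spikes 1.2 Mb apart: two loci
  ss2 <- spike_ss(data.frame(row = c(40, 160), p = c(1e-12, 1e-10)))
  loci2 <- find_loci(ss2, 4.54e-9)
  expect_equal(nrow(loci2), 2)

  # output is invariant to record order
  shuffled <- as_sumstats(as.data.frame(ss2)[sample(nrow(ss2)), ])
  loci3 <- find_loci(shuffled, 4.54e-9)
  expect_equal(as.data.frame(loci3[c("chrom", "start", "end", "index_pos")]),
               as.data.frame(loci2[c("chrom", "start", "end", "index_pos")]))
})

sim_locus <- function(causal, seed, n = 5000, m = 100, rho = 0.9) {
  cfg <- sim_config(n_samples = n, n_variants = m,
                    blocks = data.frame(length = m, rho = rho),
                    causal = causal, seed = seed)
  panel <- simulate_genotypes(cfg)
  y <- simulate_trait(panel, cfg)
  list(cfg = cfg, panel = panel, y = y,
       ss = compute_sumstats(panel, y))
}

test_that("joint estimates reproduce a multiple-regression oracle on raw genotypes", {
  sim <- sim_locus(data.frame(index = c(20, 70), ve = c(0.02, 0.02)), seed = 32)
  locus <- list(members = seq_len(nrow(sim$ss)))
  sig <- stepwise_conditional(sim$ss, sim$panel, locus, var_from_panel = TRUE)
  expect_gte(nrow(sig), 2)
  # refit the selected set on the raw genotypes
  sel <- match(sig$pos, sim$panel$variants$pos)
  fit <- lm(sim$y ~ sim$panel$dosages[, sel])
  expect_equal(unname(sig$joint_beta), unname(coef(fit)[-1]), tolerance = 1e-6)
  # signals are mutually conditionally independent at the reported threshold
  expect_true(all(sig$p_joint < 1e-8))
})

test_that("an uncorrelated candidate's conditional effect equals its marginal effect", {
  # two blocks in perfect linkage equilibrium by construction of the copula
  cfg <- sim_config(n_samples = 4000, n_variants = 2,
                    blocks = data.frame(length = c(1, 1), rho = c(0, 0)),
                    causal = data.frame(index = c(1, 2), ve = c(0.02, 0.02)),
                    seed = 33)
  panel <- simulate_genotypes(cfg)
  y <- simulate_trait(panel, cfg)
  ss <- compute_sumstats(panel, y)
  # force exact orthogonality in the reconstruction by zeroing panel LD
  R <- ld_matrix(panel)
  expect_lt(abs(R[1, 2]), 0.05)
  sig <- stepwise_conditional(ss, panel, list(members = 1:2),
                              p_joint_max = 1e-4, var_from_panel = TRUE)
  # conditional beta deviates from marginal only through the panel r
  expect_equal(sig$joint_beta, sig$beta, tolerance = 0.05)

  # with r exactly 0 the identity is algebraic: build an orthogonalised panel
  d <- panel$dosages
  c1 <- d[, 1] - mean(d[, 1])
  d[, 2] <- d[, 2] - c1 * sum(c1 * d[, 2]) / sum(c1^2)  # cov with column 1 is 0
  panel0 <- ld_panel(d, panel$variants[setdiff(names(panel$variants), "eaf")])
  R0 <- ld_matrix(panel0)
  expect_lt(abs(R0[1, 2]), 1e-10)
  sig0 <- stepwise_conditional(ss, panel0, list(members = 1:2),
                               p_joint_max = 1e-4, freq_diff_max = 1)
  expect_equal(sig0$joint_beta, sig0$beta, tolerance = 1e-10)
})

test_that("stepwise conditional analysis errors when the panel misses locus variants", {
  sim <- sim_locus(data.frame(index = 10, ve = 0.02), seed = 34, m = 20)
  short_panel <- ld_panel(sim$panel$dosages[, 1:10],
                          sim$panel$variants[1:10, setdiff(names(sim$panel$variants), "eaf")])
  expect_error(stepwise_conditional(sim$ss, short_panel, list(members = 1:20)),
               "missing")
})

test_that("nearest_gene picks the closest TSS, handles containment and ties", {
  genes <- tibble::tibble(
    chrom = c("1", "1", "1", "1"),
    txStart = c(1000000, 2000000, 3000000, 3550000),
    txEnd = c(1050000, 2100000, 3200000, 3600000),
    strand = c("+", "-", "+", "+"),
    name = c("GENEA", "GENEB", "GENEC", "GENED"))
  leads <- tibble::tibble(chrom = c("1", "1", "1", "2"),
                          pos = c(825000, 2050000, 3275000, 500))
  ann <- nearest_gene(leads, genes)
  # 175 kb upstream of GENEA's TSS, nothing closer
  expect_equal(ann$nearest_gene[1], "GENEA")
  expect_equal(ann$gene_distance[1], 175000)
  # inside GENEB's body (TSS is txEnd on the minus strand)
  expect_equal(ann$nearest_gene[2], "GENEB")
  expect_equal(ann$gene_distance[2], 0)
  # equidistant between GENEC's and GENED's TSS: smaller TSS wins
  expect_equal(abs(3000000 - 3275000), abs(3550000 - 3275000))
  expect_equal(ann$nearest_gene[3], "GENEC")
  # no gene on chromosome 2
  expect_true(is.na(ann$nearest_gene[4]))

  # gene table round-trips through the BED-like reader
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(genes, path)
  expect_equal(as.data.frame(read_gene_table(path)), as.data.frame(genes))
})
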