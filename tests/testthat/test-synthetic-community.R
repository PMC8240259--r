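small_cfg <- function(seed = 1L, ...) {
  gradient_config(stress_levels = c(0.1, 0.9), sample_ids = c("lo", "hi"),
                  n_viral_contigs = 25L, n_bacterial_contigs = 5L,
                  n_short_contigs = 3L, n_metagenome_genes = 50L,
                  seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(gradient_config(stress_levels = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(gradient_config(contig_length_range = c(5000L, 9000L)), "5000")
  expect_error(gradient_config(spacer_length = 9000L), "shortest")
  expect_error(gradient_config(mrg_rate_lytic = 1.5), "\\[0, 1\\]")
  expect_error(gradient_config(mrg_lysogen_boost = 0.5), ">= 1")
  expect_error(gradient_config(induction_noise_cv = -1), ">= 0")
  expect_error(gradient_config(stress_levels = c(0.1, 0.5), sample_ids = "only"),
               "one sample id")
})

test_that("a fixed seed reproduces the bundle byte-for-byte on disk", {
  d1 <- file.path(tempdir(), "bundle_a"); d2 <- file.path(tempdir(), "bundle_b")
  write_community_bundle(generate_community(small_cfg(seed = 5L)), d1)
  write_community_bundle(generate_community(small_cfg(seed = 5L)), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a degenerate lysogeny logit produces no lysogens and no integrase", {
  b <- generate_community(small_cfg(lysogeny_logit = c(-Inf, 0)))
  expect_false(any(b$manifest$contigs$lifestyle == "lysogenic"))
  intg <- default_integrase_list()$identifiers
  viral_genes <- b$annotations[b$annotations$contig_id %in% b$manifest$contigs$contig_id, ]
  expect_false(any(viral_genes$pfam_hit %in% intg))
})

test_that("empirical lifestyle fractions track the generative probabilities", {
  cfg <- gradient_config(stress_levels = c(0.1, 0.9), sample_ids = c("lo", "hi"),
                         n_viral_contigs = 200L, n_bacterial_contigs = 0L,
                         n_short_contigs = 0L, emit_sequences = FALSE,
                         lysogeny_logit = c(qlogis(0.1), qlogis(0.5) - qlogis(0.1)),
                         seed = 2L)
  # generative P(lysogenic) at the two stress points
  p <- plogis(cfg$lysogeny_logit[1] + cfg$lysogeny_logit[2] * c(0.1, 0.9))
  b <- generate_community(cfg)
  truth <- b$manifest$contigs
  for (i in 1:2) {
    emp <- mean(truth$lifestyle[truth$sample_id == cfg$sample_ids[i]] == "lysogenic")
    expect_lt(abs(emp - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / 200))
  }
})

test_that("planted host links appear verbatim in the spacer libraries", {
  b <- generate_community(small_cfg(seed = 9L))
  truth <- b$manifest$contigs
  sp <- b$spacers[!grepl("decoy", b$spacers$spacer_id), ]
  # every (contig, genus) truth pair has a spacer copied from that contig
  for (i in sample(nrow(truth), 10)) {
    genera <- strsplit(truth$hosts[i], ";")[[1]]
    mine <- sp[grepl(paste0("^", truth$contig_id[i], "_sp"), sp$spacer_id), ]
    expect_setequal(mine$genus, genera)
    seqchr <- as.character(b$contigs[[truth$contig_id[i]]])
    for (j in seq_len(nrow(mine))) {
      hit <- grepl(mine$sequence[j], seqchr, fixed = TRUE) ||
        grepl(rc_base(mine$sequence[j]), seqchr, fixed = TRUE)
      expect_true(hit)
    }
  }
})

test_that("induction triplets follow Vi = Vck + X B with unbiased noise", {
  t0 <- generate_induction_triplets(B = 1e6, X = 2, noise_cv = 0, vck = 1e5)
  expect_equal(t0$Vi, 2.1e6)
  expect_equal(generate_induction_triplets(B = 1e6, X = 0, noise_cv = 0, vck = 1e5)$Vi, 1e5)
  set.seed(47)
  tr <- generate_induction_triplets(B = 1e6, X = 2, noise_cv = 0.05, vck = 1e5, n = 1000)
  x_hat <- as.numeric(induced_per_cell(tr$Vi, tr$Vck, tr$B))
  expect_lt(abs(mean(x_hat) - 2) / 2, 0.01)
  expect_error(generate_induction_triplets(B = -1, X = 1), "B must be > 0")
  expect_error(generate_induction_triplets(B = 1, X = -1), "X must be >= 0")
})

test_that("bundles survive a disk round trip with identical pipeline output", {
  b <- generate_community(small_cfg(seed = 13L))
  d <- file.path(tempdir(), "bundle_rt")
  write_community_bundle(b, d)
  b2 <- read_community_bundle(d)
  expect_identical(as.character(b2$contigs), as.character(b$contigs))
  expect_equal(b2$annotations, b$annotations)
  expect_equal(b2$counts, b$counts)
  p1 <- run_virome_pipeline(b)
  p2 <- run_virome_pipeline(b2)
  expect_equal(p2$samples, p1$samples)
  unlink(d, recursive = TRUE)
})

test_that("estimated fractions are non-decreasing along a well-separated gradient", {
  ok_lys <- ok_poly <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    b <- generate_community(pattern_config(seed = 1000L + s))
    ind <- bundle_indicators(b)
    ok_lys <- ok_lys + all(diff(ind$lysogen_fraction_count) >= 0)
    m <- b$manifest$samples
    ok_poly <- ok_poly + all(diff(m$polyvalence_fraction_count) >= 0)
  }
  expect_gte(ok_lys / n_rep, 0.9)
  expect_gte(ok_poly / n_rep, 0.9)
})
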