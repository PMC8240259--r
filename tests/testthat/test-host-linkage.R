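random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

test_that("planted spacers are found at the right position and strand", {
  set.seed(1)
  bg <- random_seq(400)
  spacer <- random_seq(30)
  seq_plus <- paste0(substr(bg, 1, 100), spacer, substr(bg, 131, 400))
  seq_minus <- paste0(substr(bg, 1, 100), rc_base(spacer), substr(bg, 131, 400))
  contigs <- c(p = seq_plus, m = seq_minus)
  sp <- data.frame(spacer_id = "s1", genus = "g1", sequence = spacer,
                   stringsAsFactors = FALSE)
  links <- match_spacers(contigs, sp)
  expect_identical(links$position[links$contig_id == "p"], 101L)
  expect_identical(links$strand[links$contig_id == "p"], "+")
  expect_identical(links$position[links$contig_id == "m"], 101L)
  expect_identical(links$strand[links$contig_id == "m"], "-")
  # contig subsequence at a minus-strand link is the spacer's reverse complement
  expect_identical(rc_base(substr(seq_minus, 101, 130)), spacer)
})

test_that("non-ACGT spacers are skipped with a warning, short ones silently", {
  contigs <- c(a = random_seq(200))
  sp <- data.frame(spacer_id = c("ok", "bad", "short"),
                   genus = "g",
                   sequence = c(random_seq(25), "ACGTNNACGTACGTACGTACGTACGT",
                                "ACGTACGTAC"),
                   stringsAsFactors = FALSE)
  expect_warning(links <- match_spacers(contigs, sp), "non-ACGT")
  expect_false(any(links$spacer_id %in% c("bad", "short")))
})

test_that("matching equals the naive comparator on a mixed-width library", {
  set.seed(5)
  contigs <- stats::setNames(vapply(1:12, function(i) random_seq(600), ""),
                             sprintf("c%02d", 1:12))
  planted <- lapply(1:8, function(i) {
    ci <- sample(names(contigs), 1)
    w <- sample(c(24L, 32L), 1)
    pos <- sample(600 - w, 1)
    s <- substr(contigs[[ci]], pos, pos + w - 1)
    if (runif(1) < 0.5) s <- rc_base(s)
    data.frame(spacer_id = paste0("sp", i), genus = sample(letters[1:3], 1),
               sequence = s, stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, c(planted, list(
    data.frame(spacer_id = "decoy", genus = "a", sequence = random_seq(28),
               stringsAsFactors = FALSE))))
  got <- match_spacers(contigs, sp)
  want <- oracle_match(as.list(contigs), sp)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, names(want)], want)
})

test_that("adding a spacer never removes existing links", {
  set.seed(9)
  contigs <- stats::setNames(vapply(1:5, function(i) random_seq(500), ""),
                             paste0("c", 1:5))
  sp <- data.frame(spacer_id = "s1", genus = "g1",
                   sequence = substr(contigs[[2]], 50, 81),
                   stringsAsFactors = FALSE)
  l1 <- match_spacers(contigs, sp)
  sp2 <- rbind(sp, data.frame(spacer_id = "s2", genus = "g2",
                              sequence = substr(contigs[[4]], 100, 131)))
  l2 <- match_spacers(contigs, sp2)
  expect_true(nrow(merge(l1, l2)) == nrow(l1))
})

test_that("reverse-complementing contigs flips strands and maps coordinates", {
  set.seed(13)
  contigs <- stats::setNames(vapply(1:4, function(i) random_seq(300), ""),
                             paste0("c", 1:4))
  sp <- data.frame(spacer_id = c("f", "r"), genus = "g",
                   sequence = c(substr(contigs[[1]], 21, 52),
                                rc_base(substr(contigs[[3]], 101, 132))),
                   stringsAsFactors = FALSE)
  fwd <- match_spacers(contigs, sp)
  rcc <- stats::setNames(rc_base(unname(contigs)), names(contigs))
  rev <- match_spacers(rcc, sp)
  expect_identical(nrow(fwd), nrow(rev))
  key <- function(x) x[order(x$spacer_id), ]
  f <- key(fwd); r <- key(rev)
  expect_identical(f$contig_id, r$contig_id)
  expect_true(all(f$strand != r$strand))
  expect_identical(300L - f$position - f$match_len + 2L, r$position)
})

test_that("host-range summaries implement the >= 2 genera polyvalence rule", {
  links <- data.frame(
    contig_id = c("a", "b", "b", "b", "b", "b"),
    genus = c("Pseudomonas", "Pseudomonas", "Bacillus", "Bacillus",
              "Pseudomonas", "Bacillus"),
    spacer_id = paste0("s", 1:6), position = 1L, strand = "+",
    stringsAsFactors = FALSE)
  hr <- summarize_host_range(links)
  expect_identical(hr$n_genera, c(1L, 2L))
  expect_identical(hr$polyvalent, c(FALSE, TRUE))
  expect_identical(hr$linked_genera[2], "Bacillus;Pseudomonas")
  expect_identical(nrow(summarize_host_range(links[0, ])), 0L)
})

test_that("polyvalent fraction: weighted vs count-based, and empty case", {
  hr <- data.frame(contig_id = c("a", "b"), n_genera = c(2L, 1L),
                   polyvalent = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tpm <- c(a = 30, b = 70)
  expect_equal(polyvalent_fraction(hr, tpm), 0.30)
  expect_equal(polyvalent_fraction(hr, tpm, weighted = FALSE), 0.50)
  expect_equal(polyvalent_fraction(hr[hr$polyvalent, ], tpm), 1.0)
  expect_warning(v <- polyvalent_fraction(hr[0, ], tpm), "undefined")
  expect_true(is.na(v))
})

test_that("recovered host sets on a noiseless bundle match truth with precision 1", {
  cfg <- gradient_config(stress_levels = c(0.2, 0.8), sample_ids = c("lo", "hi"),
                         n_viral_contigs = 40L, n_bacterial_contigs = 5L,
                         n_short_contigs = 0L, seed = 21)
  b <- generate_community(cfg)
  links <- match_spacers(b$contigs, b$spacers)
  hr <- summarize_host_range(links)
  truth <- b$manifest$contigs
  expect_setequal(hr$contig_id, truth$contig_id)
  m <- match(hr$contig_id, truth$contig_id)
  expect_identical(hr$linked_genera, truth$hosts[m])
  expect_identical(hr$polyvalent, truth$polyvalent[m])
  # decoy spacers produced no links
  expect_false(any(grepl("decoy", links$spacer_id)))
})

test_that("exact-match E-value decays with match length", {
  e <- spacer_evalue(c(20, 25, 32), n = 1e7)
  expect_true(all(diff(e) < 0))
  expect_lt(e[3] / e[1], 1e-5)   # each extra base cuts E by exp(-lambda)
  expect_equal(e[1], 0.46 * 20 * 1e7 * exp(-1.28 * 20))
})
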