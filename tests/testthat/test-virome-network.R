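test_that("hypergeometric tail matches closed forms", {
  # all three clusters shared: 1 / C(10,3)
  expect_equal(hypergeometric_pvalue(3, 3, 3, 10), 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(5, 4, 0, 20), 1)
  expect_error(hypergeometric_pvalue(3, 3, 4, 10), "0 <= c")
  expect_error(hypergeometric_pvalue(11, 3, 1, 10), "a,b <= n")
  # monotone non-increasing in c
  p <- vapply(0:4, function(cc) hypergeometric_pvalue(6, 4, cc, 15), 0)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("hypergeometric tail matches subset enumeration on random small cases", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(2:12, 1); a <- sample(0:n, 1); b <- sample(0:n, 1)
    cc <- sample(0:min(a, b), 1)
    expect_equal(hypergeometric_pvalue(a, b, cc, n), oracle_hyper(a, b, cc, n),
                 tolerance = 1e-10)
  }
})

toy_assign <- list(
  g1 = c("p1", "p2", "p3", "p4"),
  g2 = c("p1", "p2", "p3", "p4"),   # identical to g1
  g3 = c("p5", "p6"),
  g4 = c("p5", "p6", "p7"),
  g5 = c("p8"),
  g6 = c("p9", "p10")
)

test_that("network edges: identical genomes connect, disjoint ones never", {
  net <- build_network(toy_assign)
  key <- paste(net$genome_a, net$genome_b)
  expect_true("g1 g2" %in% key)
  expect_false(any(grepl("g5", key)))   # g5 shares nothing with anyone
  expect_gt(net$score[key == "g1 g2"], 1)
  # independent recomputation: enumeration p-value and -log10(p T) score
  t_pairs <- attr(net, "n_pairs")
  expect_equal(t_pairs, choose(6, 2))
  n_pc <- attr(net, "n_pcs")
  for (j in seq_len(nrow(net))) {
    sa <- toy_assign[[net$genome_a[j]]]; sb <- toy_assign[[net$genome_b[j]]]
    p <- oracle_hyper(length(sa), length(sb), length(intersect(sa, sb)), n_pc)
    expect_equal(net$pvalue[j], p, tolerance = 1e-10)
    expect_equal(net$score[j], -log10(p * t_pairs), tolerance = 1e-10)
  }
})

test_that("raising the threshold only removes edges; scores are label-symmetric", {
  net1 <- build_network(toy_assign, threshold = 1)
  net2 <- build_network(toy_assign, threshold = 2)
  expect_true(all(paste(net2$genome_a, net2$genome_b) %in%
                    paste(net1$genome_a, net1$genome_b)))
  # relabelling genomes permutes but does not change the edge score multiset
  ren <- toy_assign
  names(ren) <- rev(names(ren))
  net_r <- build_network(ren)
  expect_equal(sort(net_r$score), sort(net1$score))
})

test_that("viral clusters are connected components with deterministic ids", {
  genomes <- paste0("g", 1:5)
  empty <- data.frame(genome_a = character(), genome_b = character())
  cl0 <- form_viral_clusters(empty, genomes)
  expect_identical(cl0$cluster_id, genomes)      # all singletons
  path <- data.frame(genome_a = c("g1", "g2"), genome_b = c("g2", "g3"))
  cl <- form_viral_clusters(path, genomes)
  expect_identical(cl$cluster_id[cl$genome_id %in% c("g1", "g2", "g3")],
                   rep("g1", 3))
  expect_identical(cl$cluster_id[cl$genome_id == "g4"], "g4")
})

test_that("a planted two-block structure yields exactly two clusters", {
  set.seed(23)
  block <- function(prefix, pcs) {
    stats::setNames(lapply(1:6, function(i) sample(pcs, 9)),
                    paste0(prefix, 1:6))
  }
  assign <- c(block("a", paste0("A", 1:10)), block("b", paste0("B", 1:10)))
  net <- build_network(assign)
  cl <- form_viral_clusters(net, names(assign))
  expect_identical(length(unique(cl$cluster_id)), 2L)
  expect_identical(length(unique(cl$cluster_id[grepl("^a", cl$genome_id)])), 1L)
})

test_that("reference linkage reports matched fraction and habitat composition", {
  study <- data.frame(genome_id = c("v1", "v2", "v3"), sample_id = "s1")
  reference <- data.frame(genome_id = c("r1", "r2"), habitat = c("soil", "water"))
  none <- annotate_reference_links(
    data.frame(genome_a = character(), genome_b = character()), study, reference)
  expect_equal(none$matched$matched_fraction, 0)
  edges <- data.frame(genome_a = c("v1", "v2", "v2"), genome_b = c("r1", "r1", "r2"))
  res <- annotate_reference_links(edges, study, reference)
  expect_equal(res$matched$matched_fraction, 2 / 3)
  expect_equal(res$habitats$pct[res$habitats$habitat == "soil"], 2 / 3 * 100)
  expect_equal(sum(res$habitats$pct), 100)
})

test_that("seeded reference sharing recovers the planted matched fraction", {
  set.seed(29)
  n <- 120
  shared_pool <- paste0("S", 1:5)
  linked <- runif(n) < 0.10
  assign <- stats::setNames(lapply(1:n, function(i) {
    own <- paste0("pc", i, "_", 1:6)
    if (linked[i]) c(own, shared_pool) else own
  }), paste0("v", 1:n))
  assign$ref1 <- c(shared_pool, "refonly")
  net <- build_network(assign)
  res <- annotate_reference_links(
    net, data.frame(genome_id = paste0("v", 1:n), sample_id = "s1"),
    data.frame(genome_id = "ref1", habitat = "soil"))
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(res$matched$matched_fraction - mean(linked)), 1e-9)
  expect_lt(abs(res$matched$matched_fraction - 0.10), 3 * se)
})
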