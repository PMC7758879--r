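# Small count table fixture: known counts for 10 genes and one motif.
fixture_table <- function() {
  counts <- matrix(c(2L, 0L, 1L, 3L, 0L, 0L, 4L, 1L, 0L, 2L),
                   ncol = 1, dimnames = list(sprintf("g%02d", 1:10), "m"))
  class(counts) <- c("count_table", class(counts))
  counts
}

test_that("set mean counts are plain means with strict input checking", {
  tab <- fixture_table()
  expect_equal(mean_count(tab, gene_set("s", c("g01", "g02")), "m"), 1.0)
  expect_equal(mean_count(tab, gene_set("s", "g07"), "m"), 4)
  expect_error(mean_count(tab, gene_set("s", c("g01", "gX")), "m"), "gX")
  expect_error(mean_count(tab, character(0), "m"), "empty")
  expect_error(mean_count(tab, gene_set("s", "g01"), "nope"), "nope")
})

test_that("null sets are uniform, reproducible and size-checked", {
  universe <- gene_set("u", sprintf("g%04d", 1:400))
  cfg <- mc_config(universe, n_random_sets = 300, random_set_size = 30,
                   seed = 42)
  sets <- sample_null_sets(cfg)
  expect_length(sets, 300)
  expect_true(all(lengths(sets) == 30))
  expect_true(all(vapply(sets, anyDuplicated, integer(1)) == 0))
  expect_identical(sets, sample_null_sets(cfg))  # same seed, same sets

  # per-gene inclusion frequency ~ Binomial(300, 30/400)
  freq <- table(factor(unlist(sets), levels = universe$gene_ids)) / 300
  expect_true(all(abs(freq - 30 / 400) < 5 * sqrt(0.075 * 0.925 / 300)))

  # boundary: set size equal to the universe gives degenerate nulls
  small <- mc_config(gene_set("u", sprintf("g%d", 1:5)),
                     n_random_sets = 10, random_set_size = 5, seed = 1)
  expect_true(all(vapply(sample_null_sets(small),
                         function(s) setequal(s, small$universe$gene_ids),
                         logical(1))))
  expect_error(mc_config(gene_set("u", "a"), random_set_size = 2),
               "exceeds")
})

test_that("empirical p counts strictly greater null means", {
  p <- empirical_p(5.0, rep(4.9, 2000))
  expect_equal(p$p_strict, 0)
  expect_equal(p$p_conservative, 1 / 2001)
  expect_equal(empirical_p(0, 1:10)$p_strict, 1)
  # ties count as "not higher"
  expect_equal(empirical_p(3, c(2, 3, 3, 4))$p_strict, 0.25)

  # observed at the median of a continuous null sits near 0.5
  nulls <- withr::with_seed(8, stats::rnorm(4001))
  expect_equal(empirical_p(stats::median(nulls), nulls)$p_strict, 0.5,
               tolerance = 0.01)

  # monotone: p never increases as the observed mean grows
  obs_grid <- seq(-2, 2, length.out = 41)
  ps <- vapply(obs_grid, function(o) empirical_p(o, nulls)$p_strict,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("the MC test shares nulls across motifs and is deterministic", {
  counts <- withr::with_seed(3, {
    m <- matrix(rpois(400 * 3, 1), ncol = 3,
                dimnames = list(sprintf("g%04d", 1:400),
                                c("m1", "m2", "m3")))
    class(m) <- c("count_table", class(m))
    m
  })
  cfg <- mc_config(gene_set("u", rownames(counts)), n_random_sets = 100,
                   random_set_size = 50, seed = 7)
  obs <- gene_set("obs", sprintf("g%04d", 1:40))
  t1 <- run_mc_test(counts, obs, config = cfg)
  t2 <- run_mc_test(counts, obs, config = cfg)
  expect_identical(t1, t2)  # bit-identical under the same seed

  # single sampling pass: same gene draws under every motif
  expect_length(t1$results, 3)
  for (r in t1$results) {
    expect_length(r$null_means, 100)
    expect_equal(r$p_strict, mean(r$null_means > r$observed_mean))
    # cumulative curve reaches exactly 100% at the maximum null mean
    expect_equal(r$curve$cumulative_pct[nrow(r$curve)], 100)
    expect_true(all(diff(r$curve$cumulative_pct) > 0))
    expect_true(all(diff(r$curve$mean) > 0))
  }

  # with R = 1 the strict p can only be 0 or 1
  cfg1 <- mc_config(gene_set("u", rownames(counts)), n_random_sets = 1,
                    random_set_size = 50, seed = 2)
  p1 <- run_mc_test(counts, obs, config = cfg1)$results$m1$p_strict
  expect_true(p1 %in% c(0, 1))

  missing <- mc_config(gene_set("u", c(rownames(counts), "ghost")),
                       n_random_sets = 10, random_set_size = 5, seed = 1)
  expect_error(run_mc_test(counts, obs, config = missing), "ghost")
})

test_that("enrichment p decreases as the planting rate grows", {
  motif <- consensus_motif("planted", "TTGACGTGGCAA")
  run_at_rate <- function(rate) {
    spec <- synthetic_genome_spec(
      300, motifs = list(motif), planting_rate_target = rate,
      planting_rate_background = 0.2, target_set_size = 40, seed = 99)
    bundle <- generate_genome(spec)
    promoters <- extract_promoters(bundle$genome,
                                   filter_by_length(bundle$genes))
    counts <- count_occurrences(promoters, list(motif))
    cfg <- mc_config(gene_set("u", rownames(counts)),
                     n_random_sets = 200, random_set_size = 40,
                     seed = 123)
    run_mc_test(counts, bundle$truth$target_set,
                config = cfg)$results$planted
  }
  res <- lapply(c(0.2, 0.8, 2.0), run_at_rate)
  ks <- vapply(res, `[[`, numeric(1), "k")
  expect_true(ks[1] >= ks[2] && ks[2] >= ks[3])
  expect_equal(res[[3]]$p_strict, 0)  # strong planting is detected
})

test_that("overlap accounting matches a double-loop oracle", {
  up <- gene_set("up", c("b", "c", "d"))
  down <- gene_set("down", "e")
  ref <- gene_set("ref", c("a", "b", "c"))
  rep1 <- overlap_counts(up, down, ref)
  expect_equal(rep1$n_up_overlap, 2)
  expect_equal(rep1$n_down_overlap, 0)
  expect_equal(rep1$n_reference, 3)

  disjoint <- overlap_counts(up, down, gene_set("ref2", c("x", "y")))
  expect_equal(disjoint$n_up_overlap, 0)
  expect_equal(disjoint$n_down_overlap, 0)

  expect_warning(overlap_counts(up, gene_set("down", "b"), ref),
                 "share")

  double_loop <- function(a, b) {
    n <- 0
    for (x in a) for (y in b) if (x == y) n <- n + 1
    n
  }
  pool <- sprintf("gene%03d", 1:500)
  for (i in 1:10) {
    withr::with_seed(2000 + i, {
      u <- gene_set("u", sample(pool, sample(10:200, 1)))
      d <- gene_set("d", sample(setdiff(pool, u$gene_ids),
                                sample(10:100, 1)))
      r <- gene_set("r", sample(pool, sample(10:200, 1)))
    })
    rep_i <- overlap_counts(u, d, r)
    expect_equal(rep_i$n_up_overlap, double_loop(u$gene_ids, r$gene_ids))
    expect_equal(rep_i$n_down_overlap, double_loop(d$gene_ids, r$gene_ids))
  }
})

test_that("gene sets read from text files keep order-independent content", {
  path <- write_lines_tmp(c("# upregulated genes", "g1", "g2 # trailing",
                            "", "g3"))
  gs <- read_gene_set(path, "up")
  expect_setequal(gs$gene_ids, c("g1", "g2", "g3"))
  expect_equal(gs$name, "up")
  expect_error(read_gene_set(write_lines_tmp("# only comments")), "empty")
})
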