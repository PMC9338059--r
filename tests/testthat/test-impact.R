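slope_frame <- function(ids, s37, s52, kinase = FALSE) {
  rbind(
    data.frame(protein_id = ids, gene = ids, is_kinase = kinase,
               replicate_id = 1L, temperature = 37, average_slope = s37),
    data.frame(protein_id = ids, gene = ids, is_kinase = kinase,
               replicate_id = 1L, temperature = 52, average_slope = s52))
}

test_that("impact hit rule: slope above threshold on either axis, in magnitude", {
  cfg <- run_config()   # hit_threshold 0.5, absolute rule
  imp <- proteome_impact(
    slope_frame(c("A", "B", "C"), c(0.6, 0.2, -0.7), c(0.1, 0.3, 0.0)), cfg)
  expect_equal(imp$is_hit, c(TRUE, FALSE, TRUE))
  one_sided <- proteome_impact(
    slope_frame("C", -0.7, 0.0), run_config(hit_rule = "positive"))
  expect_false(one_sided$is_hit)
})

test_that("impact slopes are replicate means; a missing temperature leaves NA", {
  df <- rbind(slope_frame("A", 0.2, 0.6),
              data.frame(protein_id = "A", gene = "A", is_kinase = FALSE,
                         replicate_id = 2L, temperature = 37,
                         average_slope = 0.4),
              data.frame(protein_id = "B", gene = "B", is_kinase = FALSE,
                         replicate_id = 1L, temperature = 37,
                         average_slope = 0.8))
  imp <- proteome_impact(df, run_config())
  expect_equal(imp$slope_37[imp$protein_id == "A"], 0.3)
  expect_true(is.na(imp$slope_52[imp$protein_id == "B"]))
  expect_true(imp$is_hit[imp$protein_id == "B"])   # called on the present axis
})

test_that("raising the hit threshold never adds hits", {
  set.seed(67)
  df <- slope_frame(sprintf("P%02d", 1:40), rnorm(40, 0, 0.5), rnorm(40, 0, 0.5))
  hits <- function(th) sum(proteome_impact(df, run_config(hit_threshold = th))$is_hit)
  expect_true(all(diff(vapply(c(0.2, 0.4, 0.6, 0.9), hits, 1)) <= 0))
})

test_that("phospho_response proportions partition and sum to one", {
  calls <- data.frame(
    entity_id = sprintf("P%d_S1", 1:4), protein_id = sprintf("P%d", 1:4),
    gene = "", site_position = 1L, residue = "S",
    slope_rep1 = 0, slope_rep2 = 0,
    category_rep1 = "NR", category_rep2 = "NR",
    final_category = c("hyper", "hypo", "biphasic", "NR"),
    mean_slope = 0, upward_intervals = 0L)
  out <- phospho_response(calls)
  expect_equal(unname(attr(out, "proportions")), rep(0.25, 4))
  expect_equal(sum(attr(out, "proportions")), 1)
  all_nr <- calls; all_nr$final_category <- "NR"
  expect_equal(unname(attr(phospho_response(all_nr), "proportions")),
               c(0, 0, 0, 1))
})

test_that("heterogeneity summary buckets proteins by their responsive category sets", {
  calls <- data.frame(
    protein_id = c("A", "A", "B", "B", "C", "C", "C", "D"),
    final_category = c("biphasic", "hypo", "hyper", "hypo",
                       "biphasic", "hyper", "hypo", "NR"))
  h <- heterogeneity_summary(calls)
  expect_equal(h$per_protein$A, c("biphasic", "hypo"))
  expect_equal(h$per_protein$B, c("hyper", "hypo"))
  counts <- h$combination_counts
  expect_equal(unname(counts[["biphasic+hypo"]]), 1L)
  expect_equal(unname(counts[["hyper+hypo"]]), 1L)
  expect_equal(unname(counts[["biphasic+hyper+hypo"]]), 1L)
  expect_equal(sum(counts), 3L)  # D has no responsive site
  single <- heterogeneity_summary(
    data.frame(protein_id = "E", final_category = "hypo"))
  expect_equal(names(single$combination_counts), "hypo")
})

test_that("hypergeometric enrichment matches the worked value and edge cases", {
  res <- hypergeom_enrichment(paste0("P", 1:4), paste0("P", 1:10),
                              list(s = paste0("P", 1:5)))
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$overlap_k, 4L)
  # empty set: k = 0, K = 0 -> p = 1
  res0 <- hypergeom_enrichment(paste0("P", 1:4), paste0("P", 1:10),
                               list(s = "Q99"))
  expect_equal(res0$p_value, 1)
  # hits are the whole background -> p = 1 for every set
  resN <- hypergeom_enrichment(paste0("P", 1:10), paste0("P", 1:10),
                               list(a = paste0("P", 1:3), b = paste0("P", 4:9)))
  expect_equal(resN$p_value, c(1, 1))
  expect_error(hypergeom_enrichment("X1", paste0("P", 1:10), list(s = "P1")),
               "input error.*X1")
})

test_that("enrichment equals exhaustive enumeration for all N <= 12", {
  for (N in c(5, 8, 12)) {
    bg <- paste0("P", seq_len(N))
    for (K in c(0, 2, N %/% 2, N)) {
      set_members <- paste0("P", seq_len(K))
      for (n in c(1, 3, N %/% 2)) {
        hits <- paste0("P", sample(N, n))   # random hit draw
        res <- hypergeom_enrichment(hits, bg, list(s = set_members))
        expect_equal(res$p_value,
                     hyper_enum_oracle(N, K, n, res$overlap_k),
                     tolerance = 1e-12,
                     label = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("enrichment p-values are probabilities, nonincreasing in k", {
  p_at <- function(k) {
    hits <- paste0("P", c(seq_len(k), 50 + seq_len(6 - k)))
    hypergeom_enrichment(hits, paste0("P", c(1:20, 51:56)),
                         list(s = paste0("P", 1:8)))$p_value
  }
  ps <- vapply(0:6, p_at, 1)
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) <= 1e-12))
})
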