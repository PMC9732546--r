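make_ct <- function(samples) {
  # samples: named list sample -> list(group, ref_h, ref_m, targets = named ct)
  do.call(rbind, lapply(names(samples), function(s) {
    x <- samples[[s]]
    rbind(
      data.frame(sample_id = s, group = x$group, gene = "TBP",
                 species_tag = c("human", "murine"),
                 ct = c(x$ref_h, x$ref_m)),
      data.frame(sample_id = s, group = x$group, gene = names(x$targets),
                 species_tag = "human", ct = unname(x$targets))
    )
  }))
}

test_that("deltaCt, reference combination and 2^deltaCt follow the printed definitions", {
  expect_equal(delta_ct(30, 25), -5)
  expect_equal(delta_ct(25, 25), 0)
  expect_equal(delta_ct(20, 25), 5)
  expect_equal(combine_references(25, 27), 26)
  expect_equal(combine_references(25, NA), 25)
  expect_equal(combine_references(25, 25), 25)
  expect_equal(n_target(0), 1)
  expect_equal(n_target(-10), 2^-10)
  expect_equal(n_target(1), 2)
})

test_that("basal normalization maps Ct 35 to 1 with one doubling per cycle", {
  ct <- make_ct(list(
    s1 = list(group = "control", ref_h = 25, ref_m = 25,
              targets = c(GENE35 = 35, GENE34 = 34, GENE25 = 25))))
  expr <- quantify_expression(ct)
  expect_equal(expr$expression[expr$gene == "GENE35"], 1)
  expect_equal(expr$expression[expr$gene == "GENE34"], 2)
  expect_equal(expr$expression[expr$gene == "GENE25"], 1024)
  # with equal references, normalized value = 2^(35 - ct) exactly, and raw
  # N_target = 2^(ref - ct)
  expect_equal(expr$n_target[expr$gene == "GENE25"], 2^0)
  # strictly decreasing in target Ct at fixed reference
  cts <- seq(20, 39, by = 0.5)
  ct2 <- make_ct(list(s1 = list(group = "g", ref_h = 26, ref_m = 26,
                                targets = setNames(cts, paste0("g", seq_along(cts))))))
  e2 <- quantify_expression(ct2)
  expect_true(all(diff(e2$expression[order(e2$ct)]) < 0))
})

test_that("dual references average and single-reference samples pass through", {
  ct <- make_ct(list(
    s1 = list(group = "g", ref_h = 24, ref_m = 26, targets = c(A = 30)),
    s2 = list(group = "g", ref_h = 25, ref_m = NA, targets = c(A = 30))))
  expr <- quantify_expression(ct)
  expect_equal(expr$reference_ct, c(25, 25))
  expect_equal(expr$n_target, c(2^-5, 2^-5))
  # cohort-median reference mode uses one shared reference Ct
  ct3 <- make_ct(list(
    s1 = list(group = "g", ref_h = 24, ref_m = 24, targets = c(A = 30)),
    s2 = list(group = "g", ref_h = 26, ref_m = 26, targets = c(A = 30)),
    s3 = list(group = "g", ref_h = 28, ref_m = 28, targets = c(A = 30))))
  e3 <- quantify_expression(ct3, reference = "cohort-median")
  expect_equal(unique(e3$reference_ct), 26)
  expect_equal(length(unique(e3$expression)), 1L)
  # samples with no detected reference are dropped with a warning
  ct4 <- make_ct(list(
    s1 = list(group = "g", ref_h = 25, ref_m = 25, targets = c(A = 30)),
    s2 = list(group = "g", ref_h = NA, ref_m = NA, targets = c(A = 30))))
  expect_warning(e4 <- quantify_expression(ct4), "dropped")
  expect_equal(unique(e4$sample_id), "s1")
})

test_that("undetected targets floor at the basal level and stay in the sample", {
  ct <- make_ct(list(
    s1 = list(group = "g", ref_h = 25, ref_m = 25,
              targets = c(A = 40, B = NA, C = 30))))
  expr <- quantify_expression(ct)
  expect_equal(expr$expression[expr$gene %in% c("A", "B")], c(1, 1))
  expect_true(all(expr$below_basal[expr$gene %in% c("A", "B")]))
  expect_false(expr$below_basal[expr$gene == "C"])
  expect_equal(nrow(expr), 3L)   # counts preserved for rank tests
})

test_that("per-gene group comparison matches enumeration and is scale-invariant", {
  # 4 vs 4 with complete separation: exact p = 2 / C(8,4)
  ct <- make_ct(c(
    lapply(setNames(31:34, paste0("c", 1:4)), function(v)
      list(group = "control", ref_h = 25, ref_m = 25, targets = c(A = v))),
    lapply(setNames(24:27, paste0("t", 1:4)), function(v)
      list(group = "treated", ref_h = 25, ref_m = 25, targets = c(A = v)))))
  expr <- quantify_expression(ct)
  cmp <- compare_expression(expr, "A", "treated")
  expect_equal(cmp$test$p_two_sided, 2 / choose(8, 4))
  expect_equal(cmp$test$p_two_sided, 0.0286, tolerance = 1e-2)
  # identical groups: p = 1, fold change 1
  ct_id <- make_ct(c(
    lapply(setNames(c(30, 31, 32), paste0("c", 1:3)), function(v)
      list(group = "control", ref_h = 25, ref_m = 25, targets = c(A = v))),
    lapply(setNames(c(30, 31, 32), paste0("t", 1:3)), function(v)
      list(group = "treated", ref_h = 25, ref_m = 25, targets = c(A = v)))))
  expr_id <- quantify_expression(ct_id)
  cmp_id <- suppressWarnings(compare_expression(expr_id, "A", "treated"))
  expect_equal(cmp_id$test$p_two_sided, 1)
  expect_equal(cmp_id$fold_change, 1)
  # rank-based p invariant under a global positive scaling of expressions
  e_scaled <- expr
  e_scaled$expression <- e_scaled$expression * 1e3
  e_scaled$n_target <- e_scaled$n_target * 1e3
  cmp_s <- compare_expression(e_scaled, "A", "treated")
  expect_equal(cmp_s$test$p_two_sided, cmp$test$p_two_sided)
  # too few samples per group is a not-evaluable condition
  expect_error(compare_expression(expr[1:3, ], "A", "treated"),
               class = "pdx_not_evaluable")
})

test_that("Ct table IO validates and round-trips", {
  ct <- simulate_ct_table(c("MKI67", "PLK1"),
                          list(treated = c(MKI67 = -2)), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_ct_table(ct, path)
  back <- read_ct_table(path)
  expect_equal(back, ct)
  bad <- ct; bad$ct <- as.character(bad$ct); bad$ct[1] <- "oops"
  badpath <- tempfile(fileext = ".csv")
  utils::write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_ct_table(badpath), class = "pdx_validation_error")
  empty <- tempfile(fileext = ".csv")
  writeLines("sample_id,group,gene,species_tag,ct", empty)
  expect_error(read_ct_table(empty), class = "pdx_validation_error")
})
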