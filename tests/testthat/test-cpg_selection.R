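test_that("exclusion masks remove the union and report per-mask counts", {
  u <- c("a", "b", "c")
  expect_equal(as.vector(apply_exclusion_masks(u, ExclusionMasks(snp_associated = "b"))),
               c("a", "c"))

  kept <- apply_exclusion_masks(u, ExclusionMasks(snp_associated = "b",
                                                  cross_reactive = c("b", "c")))
  expect_equal(as.vector(kept), "a")
  expect_equal(attr(kept, "removed_total"), 2L)
  expect_equal(attr(kept, "removed_per_mask")[["snp_associated"]], 1L)
  expect_equal(attr(kept, "removed_per_mask")[["cross_reactive"]], 2L)

  expect_equal(as.vector(apply_exclusion_masks(u, ExclusionMasks())), u)
  # mask ids absent from the universe are ignored
  expect_equal(as.vector(apply_exclusion_masks(u, ExclusionMasks(smoking = "zz"))), u)
})

test_that("cell-subset variance filter uses the population variance", {
  vals <- rbind(cg_flat = rep(0.5, 6),
                cg_var = c(0, 1, 0, 1, 0, 1),
                cg_miss = c(0.5, NA, 0.5, 0.5, 0.5, 0.5))
  colnames(vals) <- paste0("subset", 1:6)
  m <- MethylationMatrix(vals)
  res <- subset_variance_filter(m, 0.02)
  # population variance of (0,1,0,1,0,1) is 0.25 (hand-computed, divisor n)
  expect_equal(res$exclude, "cg_var")
  expect_equal(res$incomplete, "cg_miss")
  expect_length(subset_variance_filter(m, Inf)$exclude, 0)
})

test_that("per-study correlations implement the three criteria", {
  ages <- c(5, 15, 30, 50, 70, 90)
  meta <- make_meta(ages)
  vals <- rbind(lin = ages / 100,
                dec = 0.9 - sqrt(ages) / 20,        # monotone decreasing, non-linear
                logl = 0.1 + 0.15 * log(ages + 1),
                flat = rep(0.3, 6))
  colnames(vals) <- meta$sample_id
  m <- MethylationMatrix(vals)

  r_p <- per_study_correlation(m, meta, "pearson_age")
  expect_equal(unname(r_p["lin"]), 1)
  r_s <- per_study_correlation(m, meta, "spearman_age")
  expect_equal(unname(r_s["dec"]), -1)
  r_l <- per_study_correlation(m, meta, "pearson_log_age", log_offset = 1)
  expect_equal(unname(r_l["logl"]), 1)
  # zero variance -> missing, never a number
  expect_true(is.na(r_p["flat"]))
})

test_that("correlations need at least 3 complete pairs", {
  meta <- make_meta(c(10, 20, 30, 40))
  vals <- rbind(cg1 = c(0.1, 0.2, NA, NA),
                cg2 = c(0.1, 0.2, 0.3, 0.4))
  colnames(vals) <- meta$sample_id
  r <- per_study_correlation(MethylationMatrix(vals), meta, "pearson_age")
  expect_true(is.na(r["cg1"]))
  expect_equal(unname(r["cg2"]), 1)
})

test_that("candidate selection enforces every-study and sign-consistency rules", {
  ages <- seq(10, 80, length.out = 10)
  meta <- make_meta(ages)
  make_study <- function(r_signs) {
    # cg_all: strong in all studies; sign per study given by r_signs
    vals <- rbind(cg_all = 0.5 + r_signs * 0.004 * (ages - mean(ages)),
                  cg_weak = 0.5 + 0.0001 * (ages - mean(ages)) +
                    0.05 * sin(seq_along(ages)),
                  cg_null = rep(0.5, 10) + 0.01 * cos(seq_along(ages)))
    colnames(vals) <- meta$sample_id
    list(matrix = MethylationMatrix(vals), meta = meta)
  }
  # all positive in 7 studies
  coll_pos <- StudyCollection(lapply(1:7, function(i) make_study(1)))
  sel <- select_candidates(coll_pos, SelectionCriteria(methods = "pearson_age"))
  expect_true("cg_all" %in% sel$selected$pearson_age)
  expect_false("cg_weak" %in% sel$selected$pearson_age)

  # strong in six studies, flipped sign in the seventh -> excluded
  coll_mixed <- StudyCollection(c(lapply(1:6, function(i) make_study(1)),
                                  list(make_study(-1))))
  sel_mixed <- select_candidates(coll_mixed,
                                 SelectionCriteria(methods = "pearson_age"))
  # brute-force reference: per-study r computed directly with stats::cor
  r_by_study <- vapply(coll_mixed, function(s)
    cor(as.numeric(s$matrix["cg_all", ]), s$meta$age), numeric(1))
  ref_pass <- all(abs(r_by_study) >= 0.5) &&
    (all(r_by_study > 0) || all(r_by_study < 0))
  expect_false(ref_pass)
  expect_false("cg_all" %in% sel_mixed$selected$pearson_age)
})

test_that("a CpG below threshold in one study is excluded", {
  ages <- seq(20, 80, length.out = 12)
  meta <- make_meta(ages)
  strong <- function() {
    vals <- rbind(cg_q = 0.2 + 0.006 * ages)
    colnames(vals) <- meta$sample_id
    list(matrix = MethylationMatrix(vals), meta = meta)
  }
  weak <- function() {
    set.seed(99)
    vals <- rbind(cg_q = pmin(pmax(0.4 + 0.0002 * ages + rnorm(12, 0, 0.1), 0), 1))
    colnames(vals) <- meta$sample_id
    list(matrix = MethylationMatrix(vals), meta = meta)
  }
  coll <- StudyCollection(c(lapply(1:6, function(i) strong()), list(weak())))
  sel <- select_candidates(coll, SelectionCriteria(methods = "pearson_age"))
  expect_false("cg_q" %in% sel$selected$pearson_age)

  # with only strong studies it is selected
  coll2 <- StudyCollection(lapply(1:7, function(i) strong()))
  sel2 <- select_candidates(coll2, SelectionCriteria(methods = "pearson_age"))
  expect_true("cg_q" %in% sel2$selected$pearson_age)
})

test_that("selection is monotone in the cutoff and order-invariant", {
  coll <- simulate_study_collection(n_studies = 3, n_samples = 40,
                                    n_cpgs = 60, seed = 5)
  sets <- lapply(c(0.3, 0.5, 0.7), function(cut)
    select_candidates(coll, SelectionCriteria(r_cutoff = cut))$union)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))

  # permuting study order leaves the selection unchanged
  perm <- StudyCollection(unclass(coll)[c(3, 1, 2)])
  sel_a <- select_candidates(coll, SelectionCriteria())
  sel_b <- select_candidates(perm, SelectionCriteria())
  expect_setequal(sel_a$union, sel_b$union)

  # permuting sample order within a study leaves selections unchanged
  shuf <- unclass(coll)
  ord <- sample(ncol(shuf[[1]]$matrix))
  shuf[[1]]$matrix <- MethylationMatrix(unclass(shuf[[1]]$matrix)[, ord])
  sel_c <- select_candidates(StudyCollection(shuf), SelectionCriteria())
  expect_setequal(sel_a$union, sel_c$union)
})

test_that("single-study selection reduces to thresholding the correlation", {
  coll <- simulate_study_collection(n_studies = 1, n_samples = 50,
                                    n_cpgs = 80, seed = 9)
  sel <- select_candidates(coll, SelectionCriteria(methods = "pearson_age"))
  r <- per_study_correlation(coll[[1]]$matrix, coll[[1]]$meta, "pearson_age")
  expect_setequal(sel$selected$pearson_age,
                  names(r)[!is.na(r) & abs(r) >= 0.5])
})

test_that("venn partition covers the union exactly", {
  coll <- simulate_study_collection(n_studies = 2, n_samples = 60,
                                    n_cpgs = 100, seed = 11)
  sel <- select_candidates(coll, SelectionCriteria())
  expect_equal(sum(sel$venn), length(sel$union))
})
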