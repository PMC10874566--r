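meta1 <- slice_meta(mouse_id = "m1", ap_mm = 1.0, subdivision = "anterior")

cs_from_xy <- function(x, y, channel = "a", meta = meta1) {
  cell_set(channel, data.frame(id = seq_along(x), x_um = x, y_um = y,
                               area_um2 = rep(50, length(x)),
                               intensity = rep(1, length(x))), meta)
}

test_that("identical centroid lists match completely at distance zero", {
  x <- c(10, 40, 90); y <- c(15, 60, 20)
  m <- match_cells(cs_from_xy(x, y, "a"), cs_from_xy(x, y, "b"))
  expect_identical(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$dist_um == 0))
  expect_length(m$unmatched_a, 0)
  vc <- venn_counts(m)
  expect_identical(c(vc$n_a, vc$n_b, vc$n_ab), c(3L, 3L, 3L))
  expect_equal(vc$frac_ab_of_a, 1)
})

test_that("sets farther apart than the radius produce no pairs", {
  m <- match_cells(cs_from_xy(c(0, 10), c(0, 0), "a"),
                   cs_from_xy(c(100, 110), c(100, 100), "b"),
                   match_radius_um = 5)
  expect_identical(nrow(m$pairs), 0L)
  vc <- venn_counts(m)
  expect_identical(c(vc$n_a, vc$n_b, vc$n_ab), c(2L, 2L, 0L))
  expect_equal(vc$frac_ab_of_a, 0)
})

test_that("cells from different slices refuse to match", {
  meta2 <- slice_meta(mouse_id = "m2", ap_mm = 1.0, subdivision = "anterior")
  expect_error(match_cells(cs_from_xy(1, 1, "a"),
                           cs_from_xy(1, 1, "b", meta2)), "different slices")
})

test_that("jittered copies plus distractors are matched exactly and optimally", {
  set.seed(10)
  n <- 20
  x <- stats::runif(n, 0, 500); y <- stats::runif(n, 0, 500)
  # partner = jitter < radius/2, plus 5 distant distractors
  bx <- c(x + stats::runif(n, -1.7, 1.7), stats::runif(5, 600, 900))
  by <- c(y + stats::runif(n, -1.7, 1.7), stats::runif(5, 600, 900))
  m <- match_cells(cs_from_xy(x, y, "a"), cs_from_xy(bx, by, "b"),
                   match_radius_um = 5)
  expect_identical(nrow(m$pairs), 20L)
  expect_length(m$unmatched_b, 5)
})

test_that("greedy matching attains the exhaustive-optimal pair count on small instances", {
  # instances at realistic labelling separation: distinct somata are farther
  # apart than twice the match radius, partners jittered within the radius
  for (s in 1:5) {
    set.seed(s)
    n_true <- 6
    ax <- stats::runif(n_true, 0, 200); ay <- stats::runif(n_true, 0, 200)
    keep <- rep(TRUE, n_true)
    d_aa <- as.matrix(stats::dist(cbind(ax, ay)))
    for (i in seq_len(n_true - 1)) if (any(d_aa[i, -(1:i)] < 12)) keep[i] <- FALSE
    ax <- ax[keep]; ay <- ay[keep]
    bx <- c(ax + stats::runif(length(ax), -2, 2), stats::runif(2, 300, 400))
    by <- c(ay + stats::runif(length(ay), -2, 2), stats::runif(2, 300, 400))
    m <- match_cells(cs_from_xy(ax, ay, "a"), cs_from_xy(bx, by, "b"),
                     match_radius_um = 5)
    opt <- oracle_matching(ax, ay, bx, by, 5)
    expect_identical(nrow(m$pairs), opt$count)
    expect_identical(nrow(m$pairs), length(ax))
  }
})

test_that("matching conserves cells and is symmetric in count", {
  set.seed(3)
  a <- cs_from_xy(stats::runif(15, 0, 100), stats::runif(15, 0, 100), "a")
  b <- cs_from_xy(stats::runif(12, 0, 100), stats::runif(12, 0, 100), "b")
  mab <- match_cells(a, b, 10); mba <- match_cells(b, a, 10)
  expect_identical(nrow(mab$pairs), nrow(mba$pairs))
  vc <- venn_counts(mab)
  expect_identical(vc$n_a, nrow(mab$pairs) + length(mab$unmatched_a))
  expect_identical(vc$n_b, nrow(mab$pairs) + length(mab$unmatched_b))
  expect_true(all(mab$pairs$dist_um <= 10))
  expect_false(anyDuplicated(mab$pairs$id_a) > 0)
  expect_false(anyDuplicated(mab$pairs$id_b) > 0)
})

test_that("subdivision assignment follows the printed bregma ranges", {
  expect_identical(assign_subdivision(1.00), "anterior")
  expect_identical(assign_subdivision(0.00), "middle")
  expect_identical(assign_subdivision(-0.50), "posterior")
  # boundaries closed on their anterior edge
  expect_identical(assign_subdivision(c(1.80, 0.70, -0.20, -1.00)),
                   c("anterior", "middle", "posterior", "posterior"))
  expect_error(assign_subdivision(1.9), "outside")
  expect_error(assign_subdivision(-1.1), "outside")
})

test_that("configured pairwise fractions are recovered through the coloc stage", {
  # generator recovery at low / mid / high fractions, pooled over slices,
  # compared at 3 binomial standard errors
  for (f in c(0.01, 0.50, 0.87)) {
    cfg <- generator_config(seed = 1L)
    cfg$densities <- list(enriched = c(retro = 2000))
    cfg$coloc_fractions <- c("retro:Nurr1" = f)
    man <- generate_cohort(cfg, n_mice = 3, slices_per_subdivision = 2,
                           master_seed = round(1000 * f) + 7,
                           write_images = FALSE)
    slices <- attr(man, "slices")
    cellsets <- lapply(slices, function(sl) list(
      retro = cellset_from_truth(sl$truth, "retro", sl$meta),
      Nurr1 = cellset_from_truth(sl$truth, "Nurr1", sl$meta)))
    tab <- coloc_table(cellsets, "retro:Nurr1")
    n_a <- sum(tab$slices$n_a)
    expect_gte(n_a, 2000)
    pooled <- sum(tab$slices$n_ab) / n_a
    se <- sqrt(f * (1 - f) / n_a)
    expect_lt(abs(pooled - f), 3 * se + 1e-9)
  }
})

test_that("coloc tables aggregate mouse means before cohort means", {
  mk_slice <- function(mouse, ap, frac, n = 10) {
    meta <- slice_meta(mouse_id = mouse, ap_mm = ap,
                       subdivision = assign_subdivision(ap))
    x <- seq(10, 10 * n, by = 10)
    na <- n; nb_match <- round(frac * n)
    list(a = cs_from_xy(x, rep(5, na), "a", meta),
         b = cs_from_xy(x[seq_len(nb_match)], rep(5, nb_match), "b", meta))
  }
  slices <- list(mk_slice("m1", 1.0, 0.8), mk_slice("m2", 1.1, 0.9))
  tab <- coloc_table(slices, "a:b")
  # cohort mean of per-mouse fractions 0.8 and 0.9
  ant <- tab$cohort[tab$cohort$subdivision == "anterior", ]
  expect_equal(ant$mean_frac, 0.85)
  expect_identical(ant$n_mice, 2L)
  # single slice equals its Venn count
  one <- coloc_table(slices[1], "a:b")
  expect_identical(one$slices$n_ab, 8L)
  expect_equal(one$slices$frac_ab_of_a, 0.8)
})

test_that("c-Fos activation contrast recovers the configured upregulation", {
  mk_cohort <- function(fracs, condition, n_cells = 100) {
    lapply(seq_along(fracs), function(i) {
      meta <- slice_meta(mouse_id = sprintf("%s_m%d", condition, i),
                         ap_mm = 1.0, subdivision = "anterior",
                         condition = condition)
      x <- seq_len(n_cells) * 7; y <- rep(3, n_cells)
      k <- round(fracs[i] * n_cells)
      list(Nurr1 = cs_from_xy(x, y, "Nurr1", meta),
           Tle4 = cs_from_xy(x + 3.5, y + 1000, "Tle4", meta),
           cFos = cs_from_xy(x[seq_len(k)], y[seq_len(k)], "cFos", meta))
    })
  }
  naive <- mk_cohort(c(0.10, 0.11, 0.09, 0.10, 0.10), "naive")
  of <- mk_cohort(c(0.26, 0.25, 0.26, 0.25, 0.26, 0.26, 0.25, 0.26, 0.25, 0.26), "OF")
  res <- suppressWarnings(cfos_activation(naive, of, markers = "Nurr1"))
  s <- res$summary[res$summary$marker == "Nurr1", ]
  expect_equal(s$upregulation_pct, 15.6, tolerance = 0.05)
  expect_identical(s$df, 13L)
  # identical groups give zero upregulation
  same <- mk_cohort(rep(0.2, 4), "naive")
  same2 <- mk_cohort(rep(0.2, 4), "OF")
  r0 <- suppressWarnings(cfos_activation(same, same2, markers = "Nurr1"))
  expect_equal(r0$summary$upregulation_pct, 0)
  # a mouse with zero marker cells is excluded with a warning
  empty_meta <- slice_meta(mouse_id = "naive_zero", ap_mm = 1.0,
                           subdivision = "anterior", condition = "naive")
  naive_bad <- c(naive, list(list(
    Nurr1 = cs_from_xy(numeric(0), numeric(0), "Nurr1", empty_meta),
    Tle4 = cs_from_xy(1, 1, "Tle4", empty_meta),
    cFos = cs_from_xy(1, 1, "cFos", empty_meta))))
  expect_warning(cfos_activation(naive_bad, of, markers = "Nurr1"),
                 "excluded")
})
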