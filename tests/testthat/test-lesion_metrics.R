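# TLV, GLSR (with cohort summaries and mean ranks), and LDI.

test_that("tlv counts voxels and converts with the voxel volume", {
  space <- toy_space(c(5, 5, 5))
  empty <- array(0L, dim = c(5, 5, 5))
  expect_identical(tlv(empty, space), list(voxels = 0L, mm3 = 0))

  m <- empty; m[sample(125, 7)] <- 1L
  expect_identical(tlv(m, space), list(voxels = 7L, mm3 = 7))

  aniso <- toy_space(c(5, 5, 5), voxel_dims = c(0.83, 0.83, 2.2))
  expect_equal(tlv(m, aniso)$mm3, 7 * 0.83 * 0.83 * 2.2)
})

test_that("glsr is the out-of-WM proportion with flagged zero denominators", {
  wm <- array(0L, dim = c(6, 6, 6)); wm[2:5, 2:5, 2:5] <- 1L
  space <- toy_space(c(6, 6, 6), wm = wm)

  inside <- array(0L, dim = c(6, 6, 6)); inside[3:4, 3:4, 3] <- 1L
  expect_equal(glsr(inside, space)$glsr, 0)

  outside <- array(0L, dim = c(6, 6, 6)); outside[1, , ] <- 1L
  expect_equal(glsr(outside, space)$glsr, 1)

  # 10 lesion voxels, 3 outside WM -> 0.3
  m <- array(0L, dim = c(6, 6, 6))
  m[2, 2, 2:5] <- 1L; m[3, 3, 2:4] <- 1L  # 7 in WM
  m[1, 1, 1:3] <- 1L                      # 3 outside
  rec <- glsr(m, space, subject_id = "s1", registration_label = "rigid")
  expect_equal(rec$glsr, 0.3)
  expect_identical(rec$outside_wm, 3L)
  expect_identical(rec$lesion_voxels_registered, 10L)

  # native denominator
  expect_equal(glsr(m, space, denominator = "native", native_voxels = 20)$glsr,
               3 / 20)
  expect_error(glsr(m, space, denominator = "native"), "native_voxels")

  # empty mask: flagged missing, not an error
  expect_true(is.na(glsr(array(0L, dim = c(6, 6, 6)), space)$glsr))
})

test_that("dilating a mask beyond WM never decreases the GLSR numerator", {
  wm <- array(0L, dim = c(8, 8, 8)); wm[3:6, 3:6, 3:6] <- 1L
  space <- toy_space(c(8, 8, 8), wm = wm)
  set.seed(5)
  for (rep in 1:5) {
    m <- array(0L, dim = c(8, 8, 8))
    m[sample(which(wm == 1L), 6)] <- 1L
    prev_out <- glsr(m, space)$outside_wm
    for (r in 1:2) {
      d <- lesionmapr:::morph_binary(m, r, "dilate")
      expect_gte(glsr(d, space)$outside_wm, prev_out)
      prev_out <- glsr(d, space)$outside_wm
    }
  }
})

test_that("summarize_glsr: moments, MSE identity, and mean ranks", {
  recs <- data.frame(subject_id = c("a", "b", "c"),
                     registration_label = "r1", glsr = c(0, 0, 1))
  s <- summarize_glsr(recs)
  expect_equal(s$mean, 1 / 3)
  expect_equal(s$mse, 1 / 3)
  expect_equal(s$median, 0)
  expect_identical(s$n, 3L)

  # algebraic identity mse = mean^2 + population variance, random inputs
  set.seed(13)
  for (rep in 1:10) {
    g <- runif(sample(5:60, 1))
    recs <- data.frame(subject_id = seq_along(g),
                       registration_label = "x", glsr = g)
    s <- summarize_glsr(recs)
    expect_equal(s$mse, mean(g)^2 + mean((g - mean(g))^2), tolerance = 1e-12)
    expect_equal(s$mse, s$mean^2 + s$sd^2 * (length(g) - 1) / length(g),
                 tolerance = 1e-12)
  }
})

test_that("mean ranks: worked example, tie convention, rank conservation", {
  # 2 subjects x 3 algorithms, rows (0.1,0.2,0.3) and (0.3,0.2,0.1)
  long <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 3),
    registration_label = rep(c("A", "B", "C"), 2),
    glsr = c(0.1, 0.2, 0.3, 0.3, 0.2, 0.1))
  mr <- lesionmapr:::glsr_mean_ranks(long)
  expect_equal(unname(mr[c("A", "B", "C")]), c(2, 2, 2))

  # brute-force oracle on random tables, incl. ties; ranks conserve n*A(A+1)/2
  set.seed(14)
  for (rep in 1:5) {
    n <- 7; A <- 4
    long <- data.frame(
      subject_id = rep(sprintf("s%d", 1:n), each = A),
      registration_label = rep(LETTERS[1:A], n),
      glsr = sample(seq(0, 1, 0.25), n * A, replace = TRUE))
    mr <- lesionmapr:::glsr_mean_ranks(long)
    oracle <- sapply(LETTERS[1:A], function(lab) {
      mean(sapply(sprintf("s%d", 1:n), function(s) {
        rows <- long[long$subject_id == s, ]
        rank(rows$glsr)[rows$registration_label == lab]
      }))
    })
    expect_equal(mr[LETTERS[1:A]], oracle)
    expect_equal(sum(mr) * n, n * A * (A + 1) / 2)
  }

  # differing subject sets are an error for mean rank only
  bad <- long[-1, ]
  expect_error(lesionmapr:::glsr_mean_ranks(bad), "subject sets differ")
  one <- long[long$registration_label == "A", ]
  expect_no_error(summarize_glsr(one))
})

test_that("ldi matches an exhaustive per-voxel count and obeys its bounds", {
  space <- toy_space(c(5, 5, 5))
  set.seed(6)
  masks <- lapply(1:3, function(i) array(rbinom(125, 1L, 0.3), dim = c(5, 5, 5)))
  subj <- data.frame(subject_id = c("a", "b", "c"), edss = 1, age = 40,
                     sex = 1, duration = 5)
  ch <- lesion_cohort(space, subj, masks)
  prev <- lesion_count_map(ch)
  res <- ldi(ch, prev, rarity_k = 1)
  # brute force: voxel is rare for i when <= k OTHER subjects carry it
  for (i in 1:3) {
    u <- 0L
    for (v in seq_len(125)) {
      if (masks[[i]][v] == 1L) {
        others <- sum(vapply(setdiff(1:3, i), function(j) masks[[j]][v],
                             integer(1)))
        if (others <= 1L) u <- u + 1L
      }
    }
    expect_identical(res$rare_voxels[i], u)
    expect_equal(res$ldi[i], u / sum(masks[[i]]))
  }
  expect_true(all(res$ldi >= 0 & res$ldi <= 1, na.rm = TRUE))
})

test_that("ldi boundary cases and monotonicity in rarity_k", {
  space <- toy_space(c(4, 4, 4))
  shared <- array(0L, dim = c(4, 4, 4)); shared[1:2, 1, 1] <- 1L
  solo <- array(0L, dim = c(4, 4, 4)); solo[3:4, 4, 4] <- 1L
  subj <- data.frame(subject_id = c("a", "b", "c"), edss = 1, age = 40,
                     sex = 1, duration = 5)
  # a and b share all their voxels; c overlaps nobody
  ch <- lesion_cohort(space, subj, list(shared, shared, solo))
  prev <- lesion_count_map(ch)
  r0 <- ldi(ch, prev, rarity_k = 0)
  expect_equal(r0$ldi, c(0, 0, 1))  # shared -> 0 at k=0; unshared -> 1
  r1 <- ldi(ch, prev, rarity_k = 1)
  expect_equal(r1$ldi, c(1, 1, 1))  # one other subject each -> rare at k=1

  # monotone non-decreasing in rarity_k, any cohort
  ch2 <- toy_cohort(n = 6, shape = c(5, 5, 5), p = 0.4, seed = 31)
  prev2 <- lesion_count_map(ch2)
  vals <- sapply(0:5, function(k) ldi(ch2, prev2, rarity_k = k)$ldi)
  expect_true(all(apply(vals, 1, function(x) all(diff(x) >= 0)), na.rm = TRUE))

  # default rarity_k is ceiling(0.05 * (n - 1)) and is recorded
  expect_identical(attr(ldi(ch2, prev2), "rarity_k"),
                   as.integer(ceiling(0.05 * 5)))
  # subjects with empty masks get NA LDI
  ch3 <- lesion_cohort(space, subj,
                       list(shared, array(0L, dim = c(4, 4, 4)), solo))
  r3 <- ldi(ch3, lesion_count_map(ch3), rarity_k = 0)
  expect_true(is.na(r3$ldi[2]))
  # mismatched prevalence map is rejected
  expect_error(ldi(ch2, prev, rarity_k = 1), "not computed from this cohort")
})
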