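test_that("bit loads of binarized images match hand counts", {
  white <- matrix(255, 8, 8)
  job <- image_to_bits(white, 8, 8, binarization = "fixed", threshold = 127.5)
  expect_identical(job$bit_load_pct, 100)

  checker <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  job2 <- image_to_bits(checker, 8, 8, binarization = "fixed", threshold = 127.5)
  expect_identical(job2$bit_load_pct, 50)

  # known pixel counts: 13 bright pixels out of 36
  img <- matrix(0, 6, 6)
  img[sample.int(36, 13)] <- 200
  job3 <- image_to_bits(img, 6, 6, binarization = "fixed", threshold = 100)
  expect_equal(job3$bit_load_pct, 100 * 13 / 36)
})

test_that("median binarization and center-cropping behave as documented", {
  set.seed(2)
  img <- matrix(runif(400, 0, 255), 20, 20)
  job <- image_to_bits(img, 20, 20, binarization = "median")
  expect_lt(abs(job$bit_load_pct - 50), 6)
  job_crop <- image_to_bits(img, 10, 10, crop = TRUE, binarization = "fixed",
    threshold = 127.5)
  manual <- img[6:15, 6:15] > 127.5
  expect_identical(job_crop$bits, matrix(as.integer(manual), 10, 10))
})

test_that("synthetic images hit their target bit loads and the critical band", {
  imgs <- synthetic_images(100, size = 48, seed = 9)
  loads <- vapply(imgs, function(im) {
    image_to_bits(im, 48, 48, binarization = "fixed", threshold = 127.5)$bit_load_pct
  }, numeric(1))
  targets <- vapply(imgs, attr, numeric(1), "bit_load_target")
  expect_lt(max(abs(loads - targets)), 1.5)
  expect_true(all(loads >= 38 & loads <= 82))
  # histogram mode falls in the 50-70% band
  h <- hist(loads, breaks = seq(35, 85, by = 5), plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  expect_gte(mode_mid, 50)
  expect_lte(mode_mid, 70)
})

test_that("random bit matrices follow their Bernoulli rate", {
  expect_true(all(random_bits(10, 10, 1, seed = 1) == 1L))
  expect_true(all(random_bits(10, 10, 0, seed = 1) == 0L))
  b <- random_bits(400, 250, 0.5, seed = 3)
  p_hat <- mean(b)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / length(b)))
  expect_identical(random_bits(5, 5, 0.5, seed = 2), random_bits(5, 5, 0.5, seed = 2))
})

test_that("storage benchmark tabulates BER and power coherently", {
  ivs <- fixture_ivs_coarse()
  imgs <- synthetic_images(4, size = 32, seed = 6)
  res <- evaluate_storage(imgs,
    sizes = c(12L, 16L), r_int_list = c(1e4, 1e6),
    iv0 = ivs$iv0, iv1 = ivs$iv1
  )
  expect_identical(nrow(res$ber), 4L * 2L * 2L)
  # job conservation through bit-load grouping
  grouped <- storage_ber_by_load(res)
  expect_identical(sum(grouped$n_jobs), nrow(res$ber))
  # low interconnect resistance reads perfectly on these small fixtures
  expect_true(all(res$ber$ber_pct[res$ber$r_int_ohm == 1e4] == 0))
  # read power is reported for every condition
  expect_true(all(res$power$power_W > 0))
  expect_identical(nrow(res$power), 4L)
})

test_that("storage power falls from 10 kOhm to 1 MOhm on loaded arrays", {
  ivs <- fixture_ivs_coarse()
  imgs <- synthetic_images(2, size = 48, seed = 3)
  res <- evaluate_storage(imgs, sizes = 48L, r_int_list = c(1e4, 1e6),
    iv0 = ivs$iv0, iv1 = ivs$iv1)
  p <- res$power$power_W[order(res$power$r_int_ohm)]
  expect_lt(p[2], p[1])
})

test_that("a 1 MOhm interconnect degrades reads more than 100 kOhm", {
  ivs <- fixture_ivs_coarse()
  imgs <- synthetic_images(3, size = 32, seed = 14)
  res <- evaluate_storage(imgs,
    sizes = 32L, r_int_list = c(1e5, 1e6),
    iv0 = ivs$iv0, iv1 = ivs$iv1, solver = "parametric"
  )
  m <- res$ber |>
    dplyr::group_by(r_int_ohm) |>
    dplyr::summarise(ber = mean(ber_pct))
  expect_lte(m$ber[m$r_int_ohm == 1e5], m$ber[m$r_int_ohm == 1e6])
})
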