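test_that("upscale_mean averages blocks over valid cells only", {
  g <- geogrid(matrix(c(10, 30, 20, 40), 2, 2))
  expect_equal(upscale_mean(g, 2)$values, matrix(25, 1, 1))

  gc <- geogrid(matrix(7.5, 6, 6))
  expect_true(all(upscale_mean(gc, 3)$values == 7.5))

  set.seed(41)
  vals <- matrix(runif(16, 0, 100), 4, 4)
  mask <- matrix(TRUE, 4, 4)
  mask[cbind(c(1, 3, 4), c(2, 3, 1))] <- FALSE
  up <- upscale_mean(geogrid(vals, mask = mask), 2)
  expect_equal(up$values, oracle_block_means(vals, mask, 2))

  # fully masked block propagates as masked
  mask2 <- mask; mask2[1:2, 1:2] <- FALSE
  up2 <- upscale_mean(geogrid(vals, mask = mask2), 2)
  expect_false(up2$mask[1, 1])
  expect_error(upscale_mean(geogrid(vals), 0), "positive integer")
  expect_error(upscale_mean(geogrid(vals), 3), "divide")
})

test_that("upscale_mean conserves the domain mean when nothing is masked", {
  set.seed(42)
  g <- geogrid(matrix(rnorm(36 * 24), 36, 24))
  for (f in c(2, 3, 6)) expect_equal(mean(upscale_mean(g, f)$values), mean(g$values))
})

test_that("bilinear resampling is exact on constants and planes", {
  cg <- geogrid(matrix(3.5, 4, 4), res = 1)
  tg <- list(origin_lon = 0.5, origin_lat = -0.5, res = 0.4, n_lat = 6, n_lon = 6)
  out <- resample_bilinear(cg, tg)
  expect_true(all(out$values[out$mask] == 3.5))
  expect_gt(sum(out$mask), 0)

  a <- 2; b <- 3
  lons <- 0 + (1:5 - 0.5); lats <- 0 - (1:5 - 0.5)
  pg <- geogrid(outer(lats, lons, function(la, lo) a * lo + b * la),
                origin_lon = 0, origin_lat = 0, res = 1)
  tg2 <- list(origin_lon = 0.7, origin_lat = -0.7, res = 0.43, n_lat = 7, n_lon = 7)
  out2 <- resample_bilinear(pg, tg2)
  want <- outer(grid_lats(out2), grid_lons(out2), function(la, lo) a * lo + b * la)
  expect_equal(out2$values[out2$mask], want[out2$mask], tolerance = 1e-12)
})

test_that("bilinear resampling matches the textbook formula on random fields", {
  set.seed(7)
  src <- geogrid(matrix(runif(25, -10, 10), 5, 5), res = 1)
  tg <- list(origin_lon = 0.6, origin_lat = -0.6, res = 0.4, n_lat = 9, n_lon = 9)
  out <- resample_bilinear(src, tg)
  sl <- grid_lons(src); sa <- grid_lats(src)
  ol <- grid_lons(out); oa <- grid_lats(out)
  for (i in seq_len(out$n_lat)) for (j in seq_len(out$n_lon)) {
    if (!out$mask[i, j]) next
    expect_equal(out$values[i, j],
                 oracle_bilinear_point(src$values, sl, sa, ol[j], oa[i]),
                 tolerance = 1e-12)
    # interpolant stays within the hull of its four neighbours
    nb <- src$values[max(1, i %/% 2):min(5, i %/% 2 + 2),
                     max(1, j %/% 2):min(5, j %/% 2 + 2)]
    expect_gte(out$values[i, j], min(nb) - 1e-12)
    expect_lte(out$values[i, j], max(nb) + 1e-12)
  }
})

test_that("bilinear resampling masks cells adjacent to masked sources", {
  vals <- matrix(1:25, 5, 5)
  mask <- matrix(TRUE, 5, 5); mask[3, 3] <- FALSE
  src <- geogrid(vals, res = 1, mask = mask)
  tg <- list(origin_lon = 0.5, origin_lat = -0.5, res = 0.5, n_lat = 8, n_lon = 8)
  out <- resample_bilinear(src, tg)
  # masked source center is (lon 2.5, lat -2.5); targets interpolating from it
  # must be masked, targets away from it must not
  at <- function(lon, lat) {
    j <- which.min(abs(grid_lons(out) - lon))
    i <- which.min(abs(grid_lats(out) - lat))
    out$mask[i, j]
  }
  expect_false(at(2.3, -2.2))
  expect_false(at(2.7, -2.8))
  expect_true(at(4.2, -4.2))
  expect_true(at(0.8, -0.8))
  expect_error(resample_bilinear(geogrid(matrix(1, 1, 5), res = 1), tg), "degenerate")
})

test_that("QC rules mask failing cells without altering values", {
  v <- geogrid(matrix(20, 3, 3))
  qc <- list(emissivity_error = geogrid(matrix(0.01, 3, 3)),
             lst_error = geogrid(matrix(1, 3, 3)))
  qc$lst_error$values[2, 2] <- 3          # LST error 3 K > 2 K
  out <- apply_qc(v, qc, qc_rule("LST"))
  expect_false(out$mask[2, 2])
  expect_equal(sum(out$mask), 8)
  expect_equal(out$values, v$values)

  alb <- geogrid(matrix(15, 2, 2))
  out2 <- apply_qc(alb, list(flag = geogrid(matrix(0, 2, 2))), qc_rule("albedo"))
  expect_equal(out2$mask, alb$mask)

  et <- geogrid(matrix(50, 2, 2))
  cnt <- geogrid(matrix(c(36, 35, 36, 36), 2, 2))
  out3 <- apply_qc(et, list(subpixel_count = cnt), qc_rule("ET"))
  expect_false(out3$mask[2, 1])
  expect_true(all(out3$mask[cnt$values == 36]))
  expect_error(apply_qc(et, list(), qc_rule("ET")), "missing qc layer")
})

test_that("apply_qc is idempotent and only grows the mask", {
  set.seed(5)
  v <- geogrid(matrix(runif(64, 10, 30), 8, 8),
               mask = matrix(runif(64) > 0.2, 8, 8))
  qc <- list(emissivity_error = geogrid(matrix(runif(64, 0, 0.04), 8, 8)),
             lst_error = geogrid(matrix(runif(64, 0, 4), 8, 8)))
  once <- apply_qc(v, qc, qc_rule("LST"))
  twice <- apply_qc(once, qc, qc_rule("LST"))
  expect_identical(once$mask, twice$mask)
  expect_true(all(once$mask <= v$mask))
})

test_that("temporal averaging is hierarchical (mean of means)", {
  mk <- function(x) geogrid(matrix(x, 2, 2))
  expect_equal(temporal_average(rep(list(mk(4.2)), 12))$values, matrix(4.2, 2, 2))
  out <- temporal_average(list(list(day = mk(30), night = mk(20))),
                          mode = "day_night_then_annual")
  expect_equal(out$values, matrix(25, 2, 2))

  # unequal 8-day counts per month: hierarchical mean != pooled mean
  m1 <- list(mk(10), mk(20), mk(30), mk(40))   # monthly mean 25
  m2 <- list(mk(100))                          # monthly mean 100
  out2 <- temporal_average(list(m1, m2), mode = "eightday_to_monthly_to_annual")
  expect_equal(out2$values, matrix((25 + 100) / 2, 2, 2))
  expect_false(isTRUE(all.equal(out2$values[1, 1], mean(c(10, 20, 30, 40, 100)))))
  expect_error(temporal_average(list()), "empty stack")
})

test_that("temporal averaging commutes with constant scaling and honours masks", {
  set.seed(9)
  mk <- function() geogrid(matrix(runif(9), 3, 3), mask = matrix(runif(9) > 0.2, 3, 3))
  months <- replicate(6, mk(), simplify = FALSE)
  a <- temporal_average(months)
  scaled <- lapply(months, function(g) geogrid(g$values * 3, mask = g$mask))
  b <- temporal_average(scaled)
  expect_equal(b$values[b$mask], 3 * a$values[a$mask])
  expect_identical(a$mask, b$mask)
  # any-valid default: cell valid if >= 1 month valid
  expect_identical(a$mask, Reduce(`|`, lapply(months, `[[`, "mask")))
})

test_that("grids round-trip through ASCII and CSV text formats", {
  set.seed(3)
  g <- geogrid(matrix(rnorm(30), 5, 6), origin_lon = -53.2, origin_lat = -8.4,
               res = 0.05, mask = matrix(runif(30) > 0.2, 5, 6))
  fa <- tempfile(fileext = ".asc")
  write_grid_ascii(g, fa)
  g2 <- read_grid_ascii(fa)
  expect_equal(g2$values[g2$mask], g$values[g$mask], tolerance = 1e-8)
  expect_identical(g2$mask, g$mask)
  expect_equal(g2$origin_lat, g$origin_lat)

  fc <- tempfile(fileext = ".csv")
  write_grid_csv(g, fc)
  g3 <- read_grid_csv(fc)
  expect_equal(g3$values[g3$mask], g$values[g$mask], tolerance = 1e-8)
  expect_equal(grid_lons(g3), grid_lons(g))
})
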