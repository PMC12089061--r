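test_that("splitting is by volume, apportioned, disjoint, and seeded", {
  slices <- make_test_slices(20, slices_per_volume = 2, size = 64, seed = 1)
  sp <- split_dataset(slices, c(0.85, 0.05, 0.10), seed = 3)
  nvol <- function(x) length(unique(vapply(x, function(s) s$volume_id, "")))
  expect_identical(vapply(sp, nvol, 0L), c(train = 17L, val = 1L, test = 2L))
  expect_identical(sum(lengths(sp)), length(slices))

  # no volume leaks across splits
  vols <- lapply(sp, function(x) unique(vapply(x, function(s) s$volume_id, "")))
  expect_length(intersect(vols$train, c(vols$val, vols$test)), 0)
  expect_length(intersect(vols$val, vols$test), 0)

  all_train <- split_dataset(slices, c(1, 0, 0), seed = 3)
  expect_length(all_train$train, length(slices))
  expect_length(all_train$test, 0)

  sp2 <- split_dataset(slices, c(0.85, 0.05, 0.10), seed = 3)
  expect_identical(lapply(sp, lengths), lapply(sp2, lengths))
  expect_identical(vapply(sp$test, function(s) s$volume_id, ""),
                   vapply(sp2$test, function(s) s$volume_id, ""))

  expect_error(split_dataset(make_test_slices(2, size = 64, seed = 5),
                             c(0.85, 0.05, 0.10), seed = 1),
               class = "nativenoise_parameter_error")
  expect_error(split_dataset(slices, c(0.5, 0.5, 0.5)),
               class = "nativenoise_parameter_error")
})

test_that("patch extraction aligns noisy and clean windows exactly", {
  slices <- make_test_slices(2, slices_per_volume = 5, size = 64, seed = 2)
  ps <- extract_patches(slices, patch_size = 16, n_per_slice = 5, seed = 4)
  expect_identical(dim(ps$noisy)[3], 50L)
  expect_identical(dim(ps$noisy), dim(ps$clean))

  # every patch equals the (normalized) slice window at its coordinates
  by_id <- list()
  for (s in slices) {
    by_id[[sprintf("%s:%d", s$volume_id, s$slice_index)]] <- s
  }
  for (k in seq_len(dim(ps$clean)[3])) {
    s <- by_id[[ps$meta$slice_id[k]]]
    mx <- max(s$clean$pixels)
    rows <- ps$meta$row[k]:(ps$meta$row[k] + 15)
    cols <- ps$meta$col[k]:(ps$meta$col[k] + 15)
    expect_identical(ps$clean[, , k], s$clean$pixels[rows, cols] / mx)
    expect_identical(ps$noisy[, , k], s$noisy$pixels[rows, cols] / mx)
  }

  # full-slice patches
  full <- extract_patches(slices[1], patch_size = 64, n_per_slice = 1, seed = 1)
  expect_identical(full$clean[, , 1],
                   slices[[1]]$clean$pixels / max(slices[[1]]$clean$pixels))

  expect_error(extract_patches(slices, patch_size = 128),
               class = "nativenoise_parameter_error")
})

test_that("random patch centers cover all four quadrants over a volume", {
  slices <- make_test_slices(1, slices_per_volume = 8, size = 256, seed = 6)
  ps <- extract_patches(slices, patch_size = 64, n_per_slice = 5, seed = 9)
  centers_r <- ps$meta$row + 32
  centers_c <- ps$meta$col + 32
  quad <- paste(centers_r > 128, centers_c > 128)
  expect_length(unique(quad), 4)
})

test_that("patch sets round-trip through their container bit-exactly", {
  slices <- make_test_slices(2, slices_per_volume = 2, size = 64, seed = 8)
  ps <- extract_patches(slices, patch_size = 16, n_per_slice = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_patchset(ps, path)
  expect_identical(read_patchset(path), ps)

  empty <- extract_patches(list(), patch_size = 16)
  path2 <- withr::local_tempfile(fileext = ".rds")
  write_patchset(empty, path2)
  expect_identical(dim(read_patchset(path2)$noisy)[3], 0L)

  # malformed containers name the offending field
  bad <- readRDS(path)
  bad$clean <- NULL
  path3 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, path3)
  err <- tryCatch(read_patchset(path3), nativenoise_format_error = function(e) e)
  expect_match(conditionMessage(err), "clean")

  bad2 <- readRDS(path)
  bad2$noisy <- bad2$noisy[1:8, , , drop = FALSE]
  saveRDS(bad2, path3)
  expect_error(read_patchset(path3), class = "nativenoise_format_error")
})
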