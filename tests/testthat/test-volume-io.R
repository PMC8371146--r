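# NIfTI-1 and MetaImage round trips, slope/intercept scaling, and a
# cross-check against nibabel as an independent reference implementation.

test_that("NIfTI and MetaImage round-trips preserve values and affine", {
  set.seed(5)
  aff <- rbind(cbind(diag(c(0.7, 0.7, 0.6)), c(-20, 5, 3)), c(0, 0, 0, 1))
  vol <- hu_volume(array(round(rnorm(8^3, 100, 200)), rep(8, 3)), aff)
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$values, vol$values, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$affine, vol$affine, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$spacing, c(0.7, 0.7, 0.6), tolerance = 1e-6)
  }
})

test_that("constant-100 8x8x8 volume round-trips identically", {
  vol <- const_volume(100, n = 8)
  path <- file.path(tempdir(), "const.nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, vol$values, ignore_attr = TRUE)
  expect_equal(back$affine, vol$affine, ignore_attr = TRUE)
})

test_that("NIfTI scl_slope/scl_inter scaling is applied on read", {
  # hand-built int16 NIfTI with scl_slope = 2, scl_inter = 10, stored value 5
  path <- file.path(tempdir(), "scaled.nii")
  con <- file(path, "wb")
  hdr <- raw(348)
  put_i32 <- function(h, off, x) { h[(off + 1):(off + 4)] <- writeBin(as.integer(x), raw(), size = 4, endian = "little"); h }
  put_i16 <- function(h, off, x) { n <- length(x); h[(off + 1):(off + 2 * n)] <- writeBin(as.integer(x), raw(), size = 2, endian = "little"); h }
  put_f32 <- function(h, off, x) { n <- length(x); h[(off + 1):(off + 4 * n)] <- writeBin(as.double(x), raw(), size = 4, endian = "little"); h }
  hdr <- put_i32(hdr, 0, 348)
  hdr <- put_i16(hdr, 40, c(3, 3, 3, 3, 1, 1, 1, 1))
  hdr <- put_i16(hdr, 70, 4)          # int16
  hdr <- put_i16(hdr, 72, 16)         # bitpix
  hdr <- put_f32(hdr, 76, c(1, 1, 1, 1, 0, 0, 0, 0))
  hdr <- put_f32(hdr, 108, 352)       # vox_offset
  hdr <- put_f32(hdr, 112, 2)         # scl_slope
  hdr <- put_f32(hdr, 116, 10)        # scl_inter
  hdr <- put_i16(hdr, 254, 1)         # sform_code
  hdr <- put_f32(hdr, 280, c(1, 0, 0, 0))
  hdr <- put_f32(hdr, 296, c(0, 1, 0, 0))
  hdr <- put_f32(hdr, 312, c(0, 0, 1, 0))
  hdr[345:347] <- charToRaw("n+1")
  writeBin(hdr, con)
  writeBin(raw(4), con)
  writeBin(rep(5L, 27), con, size = 2, endian = "little")
  close(con)
  vol <- read_volume(path)
  expect_equal(vol$values[1, 1, 1], 20)   # 5 * 2 + 10
  expect_true(all(vol$values == 20))
})

test_that("format and validation errors are reported", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
  junk <- file.path(tempdir(), "junk.nii")
  writeBin(as.raw(1:100), junk)
  expect_error(read_volume(junk))
  txt <- file.path(tempdir(), "x.txt")
  writeLines("hi", txt)
  expect_error(read_volume(txt), "unrecognized")
})

test_that("volumes interoperate with nibabel", {
  # our writer -> nibabel reader, and nibabel writer -> our reader
  tdir <- tempdir()
  ours <- file.path(tdir, "ours.nii.gz")
  theirs <- file.path(tdir, "theirs.nii.gz")
  aff <- rbind(cbind(diag(c(0.7, 0.7, 0.6)), c(-12, 4, 2)), c(0, 0, 0, 1))
  vol <- hu_volume(array(seq_len(216) * 3 - 200, rep(6, 3)), aff)
  write_volume(vol, ours)
  script <- sprintf('
import nibabel as nib, numpy as np
img = nib.load("%s")
assert np.allclose(img.affine[:3, :], np.array([[0.7,0,0,-12],[0,0.7,0,4],[0,0,0.6,2]]), atol=1e-5), img.affine
dat = np.asanyarray(img.dataobj)
assert np.allclose(dat.ravel(order="F"), np.arange(1, 217) * 3 - 200), "data mismatch"
arr = (np.arange(60, dtype=np.float32) * 7 - 100).reshape(3, 4, 5, order="F")
out = nib.Nifti1Image(arr, img.affine[:4, :])
out.header.set_data_dtype(np.float32)
nib.save(out, "%s")
', ours, theirs)
  pys <- file.path(tdir, "xcheck.py")
  writeLines(script, pys)
  status <- system2("python", pys, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(theirs), info = paste(status, collapse = "\n"))
  back <- read_volume(theirs)
  expect_equal(back$dim, c(3L, 4L, 5L))
  want <- array(as.double(0:59 * 7 - 100), c(3, 4, 5))
  expect_equal(back$values, want, ignore_attr = TRUE)
  expect_equal(back$affine, aff, tolerance = 1e-5, ignore_attr = TRUE)
})
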