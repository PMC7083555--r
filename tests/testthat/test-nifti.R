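test_that("NIfTI round trip is bit-exact for doubles and masks", {
  x <- normdev:::with_seed(1, array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -12, -14)
  f <- tempfile(fileext = ".nii")
  write_nifti(x, f, affine = aff)
  back <- read_nifti(f)
  expect_identical(as.vector(back), as.vector(x))
  expect_equal(attr(back, "affine"), aff)

  # gzipped, 4D, float64
  x4 <- normdev:::with_seed(2, array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5)))
  fz <- tempfile(fileext = ".nii.gz")
  write_nifti(x4, fz, voxel_size = 1.5)
  b4 <- read_nifti(fz)
  expect_identical(as.vector(b4), as.vector(x4))
  expect_equal(dim(b4), dim(x4))

  # uint8 mask
  m <- array(0L, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1L
  fm <- tempfile(fileext = ".nii")
  write_nifti(m, fm, datatype = "uint8")
  bm <- read_nifti(fm)
  expect_identical(as.integer(bm), as.integer(m))
})

test_that("identical content writes identical bytes (gz included)", {
  x <- array(seq_len(60) / 7, c(3, 4, 5))
  f1 <- tempfile(fileext = ".nii.gz"); f2 <- tempfile(fileext = ".nii.gz")
  write_nifti(x, f1); Sys.sleep(0.05); write_nifti(x, f2)
  expect_identical(md5_of(f1), md5_of(f2))
})

test_that("nibabel reads our files and we read nibabel's", {
  x <- normdev:::with_seed(3, array(rnorm(2 * 3 * 4), c(2, 3, 4)))
  f <- tempfile(fileext = ".nii")
  g <- tempfile(fileext = ".nii")
  write_nifti(x, f, voxel_size = c(1, 2, 3))
  script <- sprintf(paste0(
    "import nibabel as nib\n",
    "img = nib.load(%s)\n",
    "assert img.shape == (2, 3, 4), img.shape\n",
    "nib.save(nib.Nifti1Image(img.get_fdata(), img.affine), %s)\n"),
    deparse(f), deparse(g))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  expect_true(is.null(code) || code == 0,
              info = paste(status, collapse = "\n"))
  back <- read_nifti(g)
  expect_equal(as.vector(back), as.vector(x), tolerance = 1e-12)
  expect_equal(attr(back, "voxel_size"), c(1, 2, 3), tolerance = 1e-6)
})

test_that("read_volumes enforces subject order, grids and affines", {
  cfg <- tiny_cfg(n_controls = 3, n_patients = 2, grid_shape = c(8, 8, 8))
  coh <- generate_cohort(cfg)
  gen <- generate_volumes(coh, cfg)
  vols <- gen$volumes
  dir <- tempfile(); dir.create(dir)
  maskf <- file.path(dir, "mask.nii")
  write_nifti(array(as.integer(vols$mask), dim(vols$mask)), maskf,
              affine = vols$affine, datatype = "uint8")

  # 4D route and per-subject route agree
  f4 <- file.path(dir, "all.nii")
  write_nifti(normdev:::stack_to_4d(vols$data, vols$mask), f4,
              affine = vols$affine)
  per <- vapply(seq_len(5), function(i) {
    fi <- file.path(dir, sprintf("s%d.nii", i))
    v <- array(0, dim(vols$mask)); v[vols$mask] <- vols$data[i, ]
    write_nifti(v, fi, affine = vols$affine)
    fi
  }, "")
  v1 <- read_volumes(f4, maskf, coh)
  v2 <- read_volumes(per, maskf, coh)
  expect_identical(v1$data, v2$data)
  expect_equal(v1$data, vols$data, tolerance = 1e-12)

  # missing volume names the problem; wrong grid names the offender
  expect_error(read_volumes(per[1:4], maskf, coh), "4 volume files for 5")
  wrong <- file.path(dir, "wrong.nii")
  write_nifti(array(0, c(4, 4, 4)), wrong)
  expect_error(read_volumes(c(per[1:4], wrong), maskf, coh), "grid")
})

test_that("write_map inflates in-mask vectors", {
  mask <- array(FALSE, c(4, 4, 4)); mask[2:3, 2:3, 2:3] <- TRUE
  f <- tempfile(fileext = ".nii")
  write_map(seq_len(8) / 3, diag(4), f, mask = mask)
  back <- read_nifti(f)
  expect_equal(back[mask], seq_len(8) / 3, tolerance = 1e-12)
  expect_true(all(back[!mask] == 0))
})
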