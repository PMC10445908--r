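# Stack planning, synchronized acquisition, file formats, filename codec.

test_that("frame plans follow the plane-outer channel-inner enumeration", {
  s1 <- imaging_settings(n_planes = 1,
                         channels = list(list(laser_nm = 561,
                                              intensity_pct = 20)),
                         z_start_um = 48.5)
  p1 <- plan_stack(s1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$z_um, 48.5)

  # standard stack geometry: 60 planes, 250 nm apart, two colors
  s2 <- imaging_settings(z_start_um = 40)
  p2 <- plan_stack(s2)
  expect_equal(nrow(p2), 120)
  z_per_plane <- p2$z_um[p2$channel == 0]
  expect_equal(diff(z_per_plane), rep(0.25, 59))
  expect_equal(s2$exposure_ms, 50)

  # oracle: independent nested-loop enumeration for random settings
  set.seed(9)
  for (case in 1:10) {
    n_p <- sample(1:20, 1); n_c <- sample(1:3, 1)
    dz <- stats::runif(1, 100, 600)
    z0 <- stats::runif(1, 10, 80)
    chans <- lapply(seq_len(n_c), function(i) {
      list(laser_nm = c(405, 488, 561, 640)[i], intensity_pct = 10 * i)
    })
    st <- imaging_settings(n_planes = n_p, dz_nm = dz, channels = chans,
                           z_start_um = z0)
    plan <- plan_stack(st)
    oracle <- NULL
    for (pl in 0:(n_p - 1)) for (ch in 0:(n_c - 1)) {
      oracle <- rbind(oracle, c(pl, ch, z0 + pl * dz / 1000))
    }
    expect_equal(nrow(plan), n_p * n_c) # frame-count law
    expect_equal(plan$plane, oracle[, 1])
    expect_equal(plan$channel, oracle[, 2])
    expect_equal(plan$z_um, oracle[, 3], tolerance = 1e-12)
  }

  expect_error(plan_stack(imaging_settings(n_planes = 500, z_start_um = 50)),
               "travel")
})

acquire_test_stack <- function(seed = 5, n_planes = 4, sensor = 24) {
  g <- him_test_graph(seed = seed, sensor_px = sensor, n_emitters = 10)
  acq <- g$logic_module("acquisition")
  piezo <- g$device("piezo")
  settings <- imaging_settings(
    n_planes = n_planes, z_start_um = 48.5,
    channels = list(list(laser_nm = 561, intensity_pct = 30),
                    list(laser_nm = 640, intensity_pct = 50)))
  piezo$move_to(48.5); piezo$wait_settled()
  g$sample$set_active_probe("RT01")
  out <- acq$acquire(plan_stack(settings), settings)
  list(g = g, out = out, settings = settings)
}

test_that("acquisition is synchronized: audit passes, piezo moves n-1 times", {
  x <- acquire_test_stack()
  audit <- audit_events(x$out$events)
  expect_true(audit$ok)
  expect_equal(sum(x$out$events$action == "piezo_move"), 3)
  expect_equal(sum(x$out$events$action == "exposure"), 8)
  expect_equal(dim(x$out$stack), c(24, 24, 4, 2))
  # every exposure: exactly one laser, settled hardware
  expo <- x$out$events[x$out$events$action == "exposure", ]
  expect_true(all(expo$n_lasers_on == 1))
  expect_true(all(expo$piezo_settled & expo$stage_settled))
})

test_that("an empty plan acquires an empty stack with zero triggers", {
  g <- him_test_graph(sensor_px = 16)
  acq <- g$logic_module("acquisition")
  settings <- imaging_settings(n_planes = 1, z_start_um = 50)
  plan <- plan_stack(settings)[0, ]
  out <- acq$acquire(plan, settings)
  expect_equal(dim(out$stack)[3], 0)
  expect_equal(sum(out$events$action == "exposure"), 0)
})

test_that("acquisition with a fixed seed is byte-identical on re-run", {
  a <- acquire_test_stack(seed = 11)
  b <- acquire_test_stack(seed = 11)
  expect_identical(a$out$stack, b$out$stack)
  c <- acquire_test_stack(seed = 12)
  expect_false(identical(a$out$stack, c$out$stack))
})

test_that("metadata sidecar z range equals (n_planes - 1) * dz", {
  x <- acquire_test_stack(n_planes = 6)
  expect_equal(x$out$metadata_stub$z_range_um, 5 * 0.25)
})

# minimal independent TIFF page counter: walks the IFD chain directly
tiff_page_count <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  little <- identical(magic[1:2], as.raw(c(0x49, 0x49)))
  endian <- if (little) "little" else "big"
  offset <- readBin(con, "integer", 1, size = 4, endian = endian)
  pages <- 0L
  while (offset != 0) {
    seek(con, offset)
    n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                         endian = endian)
    seek(con, offset + 2 + n_entries * 12)
    offset <- readBin(con, "integer", 1, size = 4, endian = endian)
    pages <- pages + 1L
  }
  pages
}

test_that("stacks round-trip bit-exactly through tiff, fits and raw", {
  x <- acquire_test_stack()
  md <- stack_metadata("s", x$out$metadata_stub,
                       autofocus = list(setpoint_v = 0, kp = 0.6, ki = 0.2,
                                        kd = 0, slope_v_per_um = 0.5,
                                        precision_nm = 5),
                       cycle = 1, probe = "RT01", roi_id = "001", seed = 5)
  read_back <- list()
  for (fmt in c("tiff", "fits", "raw")) {
    dir <- withr::local_tempdir()
    files <- write_stack(x$out$stack, dir, md, format = fmt)
    expect_length(files, 2)
    cube0 <- read_stack_channel(files[1])
    cube1 <- read_stack_channel(files[2])
    expect_identical(cube0, x$out$stack[, , , 1], info = paste(fmt, "ch0"))
    expect_identical(cube1, x$out$stack[, , , 2], info = paste(fmt, "ch1"))
    read_back[[fmt]] <- cube0
    if (fmt == "tiff") {
      expect_equal(tiff_page_count(files[1]), 4) # independent reader
    }
  }
  # pixel data identical across all three formats
  expect_identical(read_back$tiff, read_back$fits)
  expect_identical(read_back$tiff, read_back$raw)
})

test_that("the sidecar carries every metadata field of the acquisition record", {
  x <- acquire_test_stack()
  md <- stack_metadata("embryo-7", x$out$metadata_stub,
                       autofocus = list(setpoint_v = 0.01, kp = 0.6,
                                        ki = 0.2, kd = 0,
                                        slope_v_per_um = 0.5,
                                        precision_nm = 7.5),
                       cycle = 3, probe = "RT27", roi_id = "002", seed = 5)
  dir <- withr::local_tempdir()
  write_stack(x$out$stack, dir, md)
  sidecar <- list.files(dir, pattern = "_meta\\.yml$", full.names = TRUE)
  expect_length(sidecar, 1)
  doc <- read_stack_metadata(sidecar)
  for (field in c("sample_name", "exposure_ms", "channels", "autofocus",
                  "stage_x_um", "stage_y_um", "scan_step_nm", "z_range_um",
                  "cycle", "probe", "roi_id", "seed", "timestamp_s")) {
    expect_false(is.null(doc[[field]]), label = paste("field", field))
  }
  expect_equal(doc$autofocus$precision_nm, 7.5)
  expect_equal(doc$scan_step_nm, 250)
})

test_that("filename codec parses the deposited-data naming convention", {
  p <- parse_him_filename("scan_001_RT27_001_ROI_converted_decon_ch00.tif")
  expect_true(p$valid)
  expect_equal(p$scan, 1L)
  expect_equal(p$probe, "RT27")
  expect_equal(p$roi, "001")
  expect_equal(p$channel, 0L)
  expect_equal(p$extra_tokens, c("converted", "decon"))

  p2 <- parse_him_filename("scan_006_DAPI_001_ROI_converted_decon_ch02.tif")
  expect_equal(p2$probe, "DAPI")
  expect_equal(p2$channel, 2L)
})

test_that("format and parse are mutually inverse on random valid tuples", {
  set.seed(3)
  for (i in 1:25) {
    x <- list(scan = sample(0:999, 1), probe = paste0("RT", sample(1:99, 1)),
              roi = sample(1:999, 1), channel = sample(0:99, 1))
    name <- him_filename(x$scan, x$probe, x$roi, x$channel)
    p <- parse_him_filename(name)
    expect_true(p$valid)
    expect_equal(p$scan, x$scan)
    expect_equal(p$probe, x$probe)
    expect_equal(p$roi_index, x$roi)
    expect_equal(p$channel, x$channel)
  }
  expect_error(him_filename(1, "RT_27", 1, 0), "underscore")
  bad <- parse_him_filename("image_0042.tif")
  expect_false(bad$valid)
  expect_match(bad$reason, "scan")
})

test_that("generated names sort lexicographically in (scan, roi) order", {
  grid <- expand.grid(roi = 1:20, scan = 1:12) # roi varies fastest
  grid <- grid[order(grid$scan, grid$roi), ]
  names <- mapply(function(s, r) him_filename(s, "RT01", r, 0),
                  grid$scan, grid$roi)
  expect_identical(names, sort(names))
})
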