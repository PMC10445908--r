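# Task state machine, experiment validation, end-to-end runs, stop/pause
# semantics, status tracking and pre-analysis.

test_that("transition table drives states; invalid events are rejected unchanged", {
  expect_equal(him_transition("stopped", "start")$state, "starting")
  expect_equal(him_transition("starting", "started")$state, "running")

  r <- him_transition("running", "resume")
  expect_false(r$accepted)
  expect_equal(r$state, "running")

  expect_error(him_transition("running", "warp"), "unknown event")
  expect_error(him_transition("limbo", "start"), "unknown state")
})

test_that("every state reaches stopped; emergency stop needs at most one event", {
  tab <- him_transition_table()
  states <- unique(c(tab$from, tab$to))
  events <- unique(tab$event)
  for (s0 in states) {
    # breadth-first search over the transition table
    frontier <- s0
    seen <- s0
    found <- s0 == "stopped"
    while (!found && length(frontier) > 0) {
      nxt <- character(0)
      for (s in frontier) for (e in events) {
        r <- him_transition(s, e)
        if (r$accepted && !r$state %in% seen) {
          seen <- c(seen, r$state)
          nxt <- c(nxt, r$state)
          if (r$state == "stopped") found <- TRUE
        }
      }
      frontier <- nxt
    }
    expect_true(found, label = paste("stopped reachable from", s0))
    if (s0 != "stopped") {
      r <- him_transition(s0, "stop_emergency")
      expect_true(r$accepted)
      expect_equal(r$state, "stopped")
    }
  }
})

test_that("config validation names the offending fields", {
  dir <- withr::local_tempdir()
  cfg <- him_toy_experiment(dir)
  expect_length(validate_config(cfg), 0)

  bad <- cfg; bad$roi_file <- ""
  expect_match(validate_config(bad), "roi_file", all = FALSE)

  bad <- cfg; bad$imaging$dz_nm <- 0
  expect_match(validate_config(bad), "dz", all = FALSE)

  bad <- cfg; bad$probes <- bad$probes[1]
  expect_match(validate_config(bad), "probes", all = FALSE)

  bad <- cfg; bad$sequences$bleaching <- NULL
  expect_match(validate_config(bad), "bleaching", all = FALSE)
})

test_that("experiment configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  cfg <- him_toy_experiment(dir)
  path <- file.path(dir, "experiment.yml")
  yaml::write_yaml(list(
    task = cfg$task, sample_name = cfg$sample_name,
    save_root = cfg$save_root,
    imaging = list(exposure_ms = cfg$imaging$exposure_ms,
                   channels = cfg$imaging$channels,
                   n_planes = cfg$imaging$n_planes,
                   dz_nm = cfg$imaging$dz_nm, format = cfg$imaging$format),
    roi_file = cfg$roi_file, sequences = cfg$sequences,
    probes = cfg$probes, n_cycles = cfg$n_cycles, seed = cfg$seed), path)
  back <- experiment_config_load(path)
  expect_length(validate_config(back), 0)
  expect_equal(back$imaging$n_planes, cfg$imaging$n_planes)
  expect_equal(back$n_cycles, cfg$n_cycles)
})

run_toy <- function(dir, seed = 7, hooks = list(), n_cycles = 2,
                    status_path = NULL) {
  cfg <- him_toy_experiment(dir, seed = seed, n_cycles = n_cycles)
  g <- load_setup(him_test_setup(seed = seed, sensor_px = 24,
                                 qpd_noise_v = 0.002, n_emitters = 15))
  list(report = run_him_task(cfg, g, hooks = hooks,
                             status_path = status_path),
       graph = g, config = cfg)
}

test_that("a toy multi-cycle run produces the full file census with parseable names", {
  dir <- withr::local_tempdir()
  x <- run_toy(dir)
  rep <- x$report
  expect_equal(rep$outcome, "completed")
  files <- basename(rep$files)
  # 2 cycles x 3 ROIs x 2 channels cycle images, plus the cycle-0 set
  cycle_files <- files[!startsWith(files, "scan_000")]
  expect_length(cycle_files, 12)
  expect_length(files[startsWith(files, "scan_000")], 6)
  parsed <- lapply(files, parse_him_filename)
  expect_true(all(vapply(parsed, `[[`, logical(1), "valid")))
  # expected-schedule oracle: (cycle, roi, channel) grid in visit order
  oracle <- do.call(rbind, lapply(0:2, function(cy)
    expand.grid(channel = 0:1, roi = 1:3, cycle = cy)[, 3:1]))
  got <- data.frame(
    cycle = vapply(parsed, `[[`, integer(1), "scan"),
    roi = vapply(parsed, `[[`, integer(1), "roi_index"),
    channel = vapply(parsed, `[[`, integer(1), "channel"))
  expect_equal(got, oracle, ignore_attr = TRUE)
  # probe tokens: DAPI in cycle 0, configured probes after
  probes <- vapply(parsed, `[[`, character(1), "probe")
  expect_true(all(probes[got$cycle == 0] == "DAPI"))
  expect_true(all(probes[got$cycle == 1] == "RT01"))
  expect_true(all(probes[got$cycle == 2] == "RT02"))
})

test_that("n_cycles = 0 produces only the cycle-0 outputs", {
  dir <- withr::local_tempdir()
  x <- run_toy(dir, n_cycles = 0)
  files <- basename(x$report$files)
  expect_length(files, 6)
  expect_true(all(startsWith(files, "scan_000")))
})

test_that("identical config and seed reproduce the output tree bit for bit", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  x1 <- run_toy(d1, seed = 21)
  x2 <- run_toy(d2, seed = 21)
  h1 <- unname(tools::md5sum(x1$report$files))
  h2 <- unname(tools::md5sum(x2$report$files))
  expect_identical(basename(x1$report$files), basename(x2$report$files))
  expect_identical(h1, h2)
  expect_identical(x1$report$status_seq, x2$report$status_seq)
})

test_that("emergency stop halts immediately with lasers and pump off", {
  dir <- withr::local_tempdir()
  x <- run_toy(dir, hooks = list(
    after_roi = function(task, cycle, roi_id) {
      if (cycle == 1 && roi_id == "002") task$request_stop("emergency")
    }))
  rep <- x$report
  expect_equal(rep$outcome, "emergency_stop")
  expect_equal(rep$final_state, "stopped")
  files <- basename(rep$files)
  # ROI 3 of cycle 1 never acquired, cycle 2 absent
  expect_false(any(grepl("^scan_001_RT01_003", files)))
  expect_false(any(startsWith(files, "scan_002")))
  lasers <- x$graph$device("lasers")
  expect_true(all(lasers$intensity == 0))
  expect_false(lasers$ir_785_on)
  expect_equal(x$graph$device("pump")$pressure_mbar, 0)
})

test_that("smooth stop completes the current cycle, then stops", {
  dir <- withr::local_tempdir()
  x <- run_toy(dir, n_cycles = 3, hooks = list(
    after_roi = function(task, cycle, roi_id) {
      if (cycle == 1 && roi_id == "001") task$request_stop("smooth")
    }))
  rep <- x$report
  expect_equal(rep$final_state, "stopped")
  files <- basename(rep$files)
  # cycle 1 completes fully (all 3 ROIs), cycles 2-3 are absent
  expect_length(grep("^scan_001", files), 6)
  expect_length(grep("^scan_00[23]", files), 0)
  expect_equal(rep$n_cycles_completed, 1)
})

test_that("stop requests on a stopped task are acknowledged no-ops", {
  g <- him_test_graph()
  dir <- withr::local_tempdir()
  cfg <- him_toy_experiment(dir)
  task <- HimTask$new(g, cfg)
  expect_equal(task$state, "stopped")
  task$request_stop("smooth")
  task$request_stop("emergency")
  expect_equal(task$state, "stopped")
})

test_that("concurrent hardware commands are rejected while a task runs", {
  dir <- withr::local_tempdir()
  saw_busy <- FALSE
  x <- run_toy(dir, n_cycles = 1, hooks = list(
    after_roi = function(task, cycle, roi_id) {
      g <- task$graph
      err <- tryCatch({
        g$logic_module("fluidics")$run_step(
          injection_step("meddling", 1, 10, 100))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(err) && grepl("busy", err)) saw_busy <<- TRUE
    }))
  expect_true(saw_busy)
  expect_equal(x$report$outcome, "completed")
})

test_that("status snapshots are atomic, complete and monotone in cycle", {
  dir <- withr::local_tempdir()
  status_path <- file.path(dir, "status.yml")
  polls <- list()
  x <- run_toy(dir, status_path = status_path, hooks = list(
    after_roi = function(task, cycle, roi_id) {
      # poll mid-run the way an external tracker would
      polls[[length(polls) + 1]] <<- yaml::read_yaml(status_path)
    }))
  expect_gt(length(polls), 0)
  for (snap in polls) {
    expect_false(is.null(snap$state))
    expect_false(is.null(snap$cycle))
  }
  seq <- x$report$status_seq
  cycles <- vapply(seq, `[[`, numeric(1), "cycle")
  expect_true(all(diff(cycles) >= 0))
  # fluidics status present once injections have run
  last_fluid <- seq[[length(seq)]]$fluidics
  expect_false(is.null(last_fluid$delivered_ul))
})

test_that("status writes to an unwritable path never kill the run", {
  clock <- SimClock$new()
  lg <- SimLogger$new(clock)
  ok <- write_status(list(state = "running"),
                     "/nonexistent-dir/status.yml", logger = lg)
  expect_false(ok)
  expect_match(lg$records()$message, "status write failed", all = FALSE)
})

test_that("pre-analysis: tie rule, known focal plane, projection oracle", {
  uniform <- array(7L, dim = c(8, 8, 5))
  pre <- preanalyze_stack(uniform)
  expect_equal(pre$best_plane, 0L)
  expect_equal(length(unique(pre$sharpness)), 1)

  # a stack acquired around the focal plane: the sharpest plane must sit
  # within one plane of the emitter's true focus
  g <- him_test_graph(seed = 40, sensor_px = 32, n_emitters = 0)
  g$sample$emitters <- data.frame(
    x_um = 0, y_um = 0, z_um = 0, brightness = 500, probe = "RT01",
    laser_nm = 640, fiducial = FALSE, stringsAsFactors = FALSE)
  g$sample$set_active_probe("RT01")
  acq <- g$logic_module("acquisition")
  settings <- imaging_settings(
    n_planes = 9, dz_nm = 500, z_start_um = 48,
    channels = list(list(laser_nm = 640, intensity_pct = 100)))
  g$device("piezo")$move_to(48); g$device("piezo")$wait_settled()
  out <- acq$acquire(plan_stack(settings), settings)
  pre <- preanalyze_stack(out$stack)
  # true focus: piezo z = surface (50) + emitter z (0) -> plane 4
  expect_lte(abs(pre$best_plane - 4), 1)

  # max projection equals the brute-force elementwise maximum
  cube <- out$stack[, , , 1]
  oracle <- matrix(-Inf, nrow(cube), ncol(cube))
  for (p in seq_len(dim(cube)[3])) oracle <- pmax(oracle, cube[, , p])
  expect_equal(pre$mip, oracle)

  expect_error(preanalyze_stack(array(0L, c(4, 4, 0))), "empty")
})
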