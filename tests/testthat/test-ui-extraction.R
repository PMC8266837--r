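region_of <- function(name) {
  r <- ui_regions()
  r[r$name == name, , drop = FALSE]
}

test_that("rendered numeric boxes round-trip through template matching", {
  st <- list(frozen = TRUE, save = "none", meas_type = "AC",
             meas_value = 23.4, ti = 0.5)
  ras <- render_ui_frame(st)
  got <- read_numeric_box(ras, region_of("ac_box"))
  expect_true(got$readable)
  expect_equal(got$value, 23.4)
  expect_equal(read_numeric_box(ras, region_of("ti_box"))$value, 0.5)
  # 200 random values across all boxes
  set.seed(31)
  for (i in 1:200) {
    v <- round(stats::runif(1, 0.1, 999.9), 1)
    ty <- sample(c("HC", "AC", "FL"), 1)
    r <- render_ui_frame(list(frozen = FALSE, save = "none",
                              meas_type = ty, meas_value = v, ti = NA))
    box <- c(HC = "hc_box", AC = "ac_box", FL = "fl_box")[[ty]]
    out <- read_numeric_box(r, region_of(box))
    expect_true(out$readable)
    expect_equal(out$value, v)
  }
})

test_that("blank or corrupted regions are refused, never guessed", {
  blank <- matrix(0, ui_canvas_size()[1], ui_canvas_size()[2])
  out <- read_numeric_box(blank, region_of("hc_box"))
  expect_false(out$readable)
  expect_true(is.na(out$value))
  ras <- render_ui_frame(list(frozen = FALSE, save = "none",
                              meas_type = "HC", meas_value = 187.3,
                              ti = NA))
  r <- region_of("hc_box")
  ras2 <- ras
  ras2[r$row0:r$row1, r$col0 + 1] <- 0 # zero the first glyph column
  out2 <- read_numeric_box(ras2, r)
  expect_false(out2$readable)
  expect_true(is.na(out2$value))
  expect_error(read_numeric_box(ras, data.frame(row0 = 5, col0 = 5,
                                                row1 = 4, col1 = 4)),
               "empty region")
})

test_that("freeze state changes only the freeze indicator region", {
  a <- render_ui_frame(list(frozen = TRUE, save = "none",
                            meas_type = NA, meas_value = NA, ti = 0.4))
  b <- render_ui_frame(list(frozen = FALSE, save = "none",
                            meas_type = NA, meas_value = NA, ti = 0.4))
  d <- which(a != b, arr.ind = TRUE)
  r <- region_of("freeze_box")
  expect_gt(nrow(d), 0)
  expect_true(all(d[, 1] >= r$row0 & d[, 1] <= r$row1 &
                    d[, 2] >= r$col0 & d[, 2] <= r$col1))
})

test_that("freeze transition detection equals the first-difference oracle", {
  ui <- data.frame(frame = 0:149, frozen = FALSE)
  ui$frozen[101:150] <- TRUE
  ev <- detect_freeze_transitions(ui)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "freeze_on")
  expect_equal(ev$frame, 100L)
  expect_equal(ev$t, 100 / 30)
  expect_equal(nrow(detect_freeze_transitions(
    data.frame(frame = 0:99, frozen = TRUE))), 0)
  set.seed(12)
  for (i in 1:20) {
    ui <- data.frame(frame = 0:299,
                     frozen = stats::runif(300) < 0.3)
    ev <- detect_freeze_transitions(ui)
    orc <- oracle_freeze_events(ui$frozen, ui$frame)
    expect_equal(ev$kind, orc$kind)
    expect_equal(ev$frame, orc$frame)
    # on/off strictly alternate
    on <- ev$kind == "freeze_on"
    if (nrow(ev) > 1) expect_true(all(diff(on) != 0))
  }
})

test_that("structured-mode extraction recovers generator events exactly", {
  s <- tiny_session(seed = 13, duration_min = 4)
  ev <- extract_event_timeline(s$ui)
  expect_equal(ev$kind, s$events$kind)
  expect_equal(ev$t, s$events$t)
  expect_equal(ev$frame, s$events$frame)
  expect_equal(ev$meas_value, s$events$meas_value)
  # saves only while frozen (generator convention survives the channel)
  sv <- ev[ev$kind %in% c("image_save", "clip_save"), ]
  for (t in sv$t)
    expect_true(any(s$freezes$t_on <= t & t < s$freezes$t_off))
})

test_that("raster-mode extraction equals structured mode on clean renders", {
  cfg <- tiny_config(seed = 14)
  s <- simulate_session(cfg, duration_min = 0.5, streams = "ui")
  rasters <- lapply(seq_len(nrow(s$ui)), function(i)
    render_ui_frame(s$ui[i, ]))
  ev_r <- extract_event_timeline(rasters, frame_rate = cfg$frame_rate)
  ev_s <- extract_event_timeline(s$ui, frame_rate = cfg$frame_rate)
  expect_equal(ev_r$kind, ev_s$kind)
  expect_equal(ev_r$t, ev_s$t)
  expect_equal(ev_r$meas_type, ev_s$meas_type)
  expect_equal(ev_r$meas_value, ev_s$meas_value)
  # PNG round trip preserves the channel
  dir <- withr::local_tempdir()
  write_ui_frames(rasters[1:30], dir)
  back <- read_ui_frames(dir)
  expect_equal(back, rasters[1:30])
})

test_that("biometric measurement counts match the per-scan plan", {
  expect_equal(count_biometric_measurements(
    data.frame(kind = character(), meas_type = character()))$total, 0)
  set.seed(15)
  plans <- list(c(HC = 2L, AC = 3L, FL = 1L), c(HC = 0L, AC = 1L, FL = 2L))
  tot <- c(HC = 0L, AC = 0L, FL = 0L)
  for (k in seq_along(plans)) {
    cfg <- tiny_config(seed = 15 + k)
    s <- simulate_session(cfg, duration_min = 4, streams = "ui",
                          measurement_plan = plans[[k]])
    cnt <- count_biometric_measurements(extract_event_timeline(s$ui))
    for (ty in names(tot)) tot[ty] <- tot[ty] + cnt[[ty]]
  }
  expect_equal(as.integer(tot), as.integer(Reduce(`+`, plans)))
})
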