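#' Ernst angle for a spoiled GRE acquisition
#'
#' `acos(exp(-TR/T1))` in degrees — the flip angle maximizing spoiled-GRE
#' signal.  White-matter / deep-gray T1 presets: 650, 850 and 1220 ms at
#' 1.5, 3 and 7 T.
#'
#' @param tr Repetition time in seconds (>= 0).
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @return Angle in degrees.
#' @export
ernst_angle <- function(tr, t1) {
  if (any(t1 <= 0)) stop("t1 must be > 0")
  if (any(tr < 0)) stop("tr must be >= 0")
  acos(exp(-tr / t1)) * 180 / pi
}

#' Reference T1 / T2* values by field strength
#'
#' T1 of white matter / deep gray matter (650, 850, 1220 ms) and T2* of the
#' putamen (55, 30, 16 ms) at 1.5, 3 and 7 T.
#'
#' @param field_strength 1.5, 3 or 7 (tesla).
#' @return Value in seconds.
#' @export
t1_preset <- function(field_strength) {
  switch(as.character(field_strength),
         "1.5" = 0.650, "3" = 0.850, "7" = 1.220,
         stop("no T1 preset for ", field_strength, " T"))
}

#' @rdname t1_preset
#' @export
t2star_preset <- function(field_strength) {
  switch(as.character(field_strength),
         "1.5" = 0.055, "3" = 0.030, "7" = 0.016,
         stop("no T2* preset for ", field_strength, " T"))
}

protocol_check <- function(item, status, detail) {
  data.frame(item = item, status = status, detail = detail)
}

#' Build and check a uniform echo train
#'
#' TEs are `te1 + k * delta_te` for `k = 0 .. n_echoes - 1`.  Checks: the
#' last TE should reach the target tissue's T2* (pass; warn when within 10%
#' below; fail otherwise) and at least three echoes should be acquired.
#'
#' @param te1 First echo time in seconds (> 0).
#' @param delta_te Uniform echo spacing in seconds (> 0).
#' @param n_echoes Number of echoes (>= 1).
#' @param t2star_target Target T2* in seconds (e.g. [t2star_preset()]).
#' @return List with `te` (seconds) and `checks` (a data.frame of
#'   item/status/detail rows).
#' @export
echo_train <- function(te1, delta_te, n_echoes, t2star_target = NULL) {
  if (te1 <= 0 || delta_te <= 0 || n_echoes < 1)
    stop("te1 and delta_te must be positive and n_echoes >= 1")
  te <- te1 + delta_te * (seq_len(n_echoes) - 1)
  checks <- protocol_check(
    "echo count (three or more echoes)",
    if (n_echoes >= 3) "pass" else "fail",
    sprintf("%d echoes acquired", n_echoes))
  if (!is.null(t2star_target)) {
    last <- te[n_echoes]
    status <- if (last >= t2star_target) "pass"
    else if (last >= 0.9 * t2star_target) "warn"
    else "fail"
    checks <- rbind(checks, protocol_check(
      "last TE at least tissue T2*", status,
      sprintf("last TE %.4g ms vs target %.4g ms", last * 1e3,
              t2star_target * 1e3)))
  }
  list(te = te, checks = checks)
}

#' Fat-water shift in pixels
#'
#' `3.5 ppm * 42.577 MHz/T * B0 / bandwidth`, the chemical-shift
#' displacement of fat in readout pixels; 220 Hz/pixel at 3 T gives the
#' conventional two-pixel shift.
#'
#' @param bandwidth_hz_per_pixel Readout bandwidth in Hz/pixel (> 0).
#' @param b0 Field strength in tesla.
#' @return List with `raw` (pixels) and `pixels` (nearest integer).
#' @export
fatwater_shift_pixels <- function(bandwidth_hz_per_pixel, b0) {
  if (bandwidth_hz_per_pixel <= 0) stop("bandwidth must be > 0")
  raw <- 3.5 * 42.577 * b0 / bandwidth_hz_per_pixel
  list(raw = raw, pixels = round(raw))
}

report_item <- function(section, item, value, essential) {
  data.frame(section = section, item = item,
             value = as.character(value), essential = essential,
             missing = is.na(value) || !nzchar(as.character(value)))
}

#' Consensus-style reporting bundle
#'
#' Assembles the hardware, sequence and pipeline reporting items (with an
#' essential/optional marking per item) from the acquisition metadata, the
#' pipeline configuration and the per-stage provenance records, flags any
#' missing essential item, and produces a ready-to-paste methods paragraph.
#' Parameter values are listed even when they are the defaults.
#'
#' @param meta [acquisition_meta()].
#' @param config [pipeline_config()].
#' @param provenance Optional list of per-stage records (as produced by
#'   [run_pipeline()]); stage algorithm names and parameters are folded
#'   into the pipeline section.
#' @return An object of class `qsm_report` with `items` (data.frame),
#'   `complete`, `missing_essentials` and `methods_text`.
#' @export
build_report <- function(meta, config, provenance = NULL) {
  fmt <- function(x) if (is.null(x) || length(x) == 0 || all(is.na(x)))
    NA_character_ else paste(signif(unlist(x), 6), collapse = ", ")
  te_ms <- signif(meta$te * 1e3, 4)
  te_desc <- if (length(meta$te) >= 2 && has_uniform_spacing(meta$te))
    sprintf("%d echoes, TE = %g:%g:%g ms", length(meta$te), te_ms[1],
            signif(diff(meta$te)[1] * 1e3, 4), te_ms[length(te_ms)])
  else sprintf("%d echo(es), TE = %s ms", length(meta$te),
               paste(te_ms, collapse = ", "))

  items <- rbind(
    report_item("hardware", "Field strength [T]", fmt(meta$field_strength), TRUE),
    report_item("hardware", "Vendor", if (is.na(meta$vendor)) NA_character_ else meta$vendor, TRUE),
    report_item("hardware", "Scanner model", if (is.na(meta$model)) NA_character_ else meta$model, FALSE),
    report_item("hardware", "Software release", if (is.na(meta$software)) NA_character_ else meta$software, FALSE),
    report_item("sequence", "Acquisition sequence type", "3D multi-echo RF-spoiled GRE", TRUE),
    report_item("sequence", "Number of echoes and TEs", te_desc, TRUE),
    report_item("sequence", "TR [s]", fmt(meta$tr), TRUE),
    report_item("sequence", "Flip angle [deg]", fmt(meta$flip_angle), FALSE),
    report_item("sequence", "Voxel size [mm]", fmt(meta$voxel_size), TRUE),
    report_item("sequence", "Acceleration", "none (simulated)", TRUE),
    report_item("sequence", "Scan duration", "n/a (simulated)", TRUE),
    report_item("pipeline", "Toolbox", paste0("qsmr ", utils::packageVersion("qsmr")), TRUE),
    report_item("pipeline", "Echo combination", config$fieldmap_method, TRUE),
    report_item("pipeline", "Phase unwrapping", "quality-guided region growing (exact)", TRUE),
    report_item("pipeline", "Masking", sprintf(
      "Otsu + largest component + closing; quality factor %g; erosion %d voxel(s); holes %s",
      config$mask_quality_factor, config$mask_erode_voxels,
      if (config$mask_reintroduce_holes) "reintroduced" else "filled"), TRUE),
    report_item("pipeline", "Background field removal", switch(
      config$bg_method,
      vsharp = sprintf("V-SHARP, radii %s mm, TSVD %g",
                       paste(range(config$vsharp_radii_mm), collapse = "-"),
                       config$vsharp_tsvd),
      pdf = sprintf("PDF, tol %g, max %d iterations", config$pdf_tol,
                    config$pdf_max_iter)), TRUE),
    report_item("pipeline", "Dipole inversion", switch(
      config$inversion_method,
      tv = sprintf("TV-regularized, lambda %g, consistency weight %g, max %d iterations",
                   config$tv_lambda, config$tv_mu, config$tv_max_iter),
      tkd = sprintf("TKD, threshold %g", config$tkd_threshold)), TRUE),
    report_item("pipeline", "Reference region", config$reference_region, TRUE),
    report_item("pipeline", "Display window [ppm]", fmt(config$display_window_ppm), FALSE))

  if (!is.null(provenance)) {
    for (st in provenance) {
      items <- rbind(items, report_item(
        "provenance", paste0("stage:", st$stage),
        paste0(st$algorithm, if (length(st$params))
          paste0(" (", paste(names(st$params),
                             vapply(st$params, function(p)
                               paste(vapply(unlist(p), function(v)
            if (is.numeric(v)) as.character(signif(v, 6))
            else as.character(v), character(1)), collapse = ","),
                               character(1)),
                             sep = "=", collapse = "; "), ")") else ""),
        FALSE))
    }
  }
  missing <- items$item[items$essential & items$missing]
  methods_text <- sprintf(
    paste0("Multi-echo GRE data (%s; TR = %s s; flip angle %s deg; voxel ",
           "size %s mm) were processed with qsmr: %s echo combination with ",
           "quality-guided exact spatial unwrapping, four-stage masking, %s ",
           "background-field removal and %s dipole inversion. ",
           "Susceptibility values are expressed in ppm referenced to the %s."),
    te_desc, fmt(meta$tr), fmt(meta$flip_angle), fmt(meta$voxel_size),
    config$fieldmap_method,
    switch(config$bg_method, vsharp = "V-SHARP", pdf = "PDF"),
    if (config$inversion_method == "tv")
      sprintf("TV-regularized (lambda = %g, consistency weight = %g)",
              config$tv_lambda, config$tv_mu)
    else sprintf("TKD (threshold = %g)", config$tkd_threshold),
    if (config$reference_region == "wholebrain") "whole-brain mask"
    else config$reference_region)
  structure(
    list(items = items, complete = length(missing) == 0,
         missing_essentials = missing, methods_text = methods_text),
    class = "qsm_report")
}

#' @export
print.qsm_report <- function(x, ...) {
  cat("<qsm_report>", nrow(x$items), "items;",
      if (x$complete) "complete\n"
      else paste0("INCOMPLETE, missing: ",
                  paste(x$missing_essentials, collapse = ", "), "\n"))
  invisible(x)
}

#' Serialize a report bundle
#'
#' @param report A `qsm_report`.
#' @param path Output path; format chosen by extension (`.json` or `.md`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(items = report$items, complete = report$complete,
           missing_essentials = report$missing_essentials,
           methods_text = report$methods_text),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c("# QSM reporting bundle", "",
               paste0("Complete: ", report$complete), "")
    for (sec in unique(report$items$section)) {
      lines <- c(lines, paste0("## ", sec), "")
      sub <- report$items[report$items$section == sec, ]
      lines <- c(lines, sprintf("- %s%s: %s", sub$item,
                                ifelse(sub$essential, " (essential)", ""),
                                ifelse(sub$missing, "MISSING", sub$value)),
                 "")
    }
    lines <- c(lines, "## Methods text", "", report$methods_text)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Check a protocol sidecar against the acquisition recommendations
#'
#' Runs the calculator-based checks on a metadata object: echo count and
#' last-TE coverage, Ernst-angle proximity, TR exceeding the last echo
#' (plus a rewinder margin), and uniform echo spacing.
#'
#' @param meta [acquisition_meta()].
#' @param rewinder_margin_s TR margin beyond the last TE (default 3 ms).
#' @return data.frame of item/status/detail checks.
#' @export
protocol_check_meta <- function(meta, rewinder_margin_s = 0.003) {
  b0 <- meta$field_strength
  t2s <- tryCatch(t2star_preset(b0), error = function(e) NULL)
  et <- echo_train(meta$te[1],
                   if (length(meta$te) > 1) diff(meta$te)[1] else meta$te[1],
                   length(meta$te), t2s)
  checks <- et$checks
  checks <- rbind(checks, protocol_check(
    "uniform echo spacing",
    if (has_uniform_spacing(meta$te)) "pass" else "warn",
    paste("spacings [ms]:",
          paste(signif(diff(meta$te) * 1e3, 4), collapse = ", "))))
  if (!is.na(meta$tr)) {
    ok <- meta$tr > tail(meta$te, 1) + rewinder_margin_s
    checks <- rbind(checks, protocol_check(
      "TR exceeds last TE plus rewinder margin",
      if (ok) "pass" else "fail",
      sprintf("TR %.4g ms vs last TE %.4g ms", meta$tr * 1e3,
              tail(meta$te, 1) * 1e3)))
  }
  t1 <- tryCatch(t1_preset(b0), error = function(e) NULL)
  if (!is.null(t1) && !is.na(meta$flip_angle) && !is.na(meta$tr)) {
    ernst <- ernst_angle(meta$tr, t1)
    dev <- abs(meta$flip_angle - ernst)
    checks <- rbind(checks, protocol_check(
      "flip angle near Ernst angle",
      if (dev <= 3) "pass" else "warn",
      sprintf("flip %.3g deg vs Ernst %.3g deg (T1 = %g ms)",
              meta$flip_angle, ernst, t1 * 1e3)))
  }
  checks
}
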