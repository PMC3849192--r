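## CSV input/output, schema validation, packaged validation tables, and the
## batch pipeline behind the command-line interface.

kpuu_schemas <- list(
  table2 = c("compound", "class", "fu_homog_mean", "fu_homog_sd",
             "fu_slice_mean", "fu_slice_sd", "invitro_1h", "invitro_ss",
             "invivo_homog", "invivo_slice"),
  table3 = c("compound", "invitro_1h", "invitro_ss", "invivo_slice"),
  transwell = c("compound", "c_d0", "c_d_t", "c_r_t", "t_min", "sucrose_frac"),
  profile = c("time_min", "conc_nm")
)

#' Load and validate a compound table
#'
#' Reads a CSV against one of the package's column schemas
#' (case-insensitive headers), coerces numeric columns with row-level error
#' reporting, and returns typed records. Character columns named `compound`
#' must be nonempty. A write-read round trip through
#' [write_compound_table()] is lossless.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"table2"` (binding fractions plus in vitro/in vivo
#'   ratios), `"table3"` (in vitro/in vivo ratios only), `"transwell"`
#'   (raw donor/receiver concentrations per insert), `"profile"`
#'   (time/concentration pairs).
#' @return A data frame with canonical lower-case column names.
#' @examples
#' load_compound_table(
#'   system.file("extdata", "table2_drugs.csv", package = "kpuu"), "table2")
#' @export
load_compound_table <- function(path, schema = c("table2", "table3",
                                                 "transwell", "profile")) {
  schema <- match.arg(schema)
  required <- kpuu_schemas[[schema]]
  if (!file.exists(path)) stop_kpuu(sprintf("file not found: %s", path))
  df <- tryCatch(read.csv(path, check.names = FALSE, strip.white = TRUE),
                 error = function(e) {
                   stop_kpuu(sprintf("schema error reading %s: %s",
                                     path, conditionMessage(e)))
                 })
  if (nrow(df) == 0L && ncol(df) == 0L) {
    stop_kpuu(sprintf("schema error: %s is empty", path))
  }
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_kpuu(sprintf("schema error: missing column `%s`", missing[[1L]]))
  }
  df <- df[required]
  character_cols <- intersect(c("compound", "class"), required)
  for (col in setdiff(required, character_cols)) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "" | raw == "NA"))
    if (length(bad)) {
      stop_kpuu(sprintf("non-numeric value `%s` in column `%s`, row %d",
                        raw[bad[[1L]]], col, bad[[1L]]))
    }
    neg <- which(val < 0)
    if (length(neg)) {
      stop_kpuu(sprintf("negative value in column `%s`, row %d", col, neg[[1L]]))
    }
    df[[col]] <- val
  }
  if ("compound" %in% names(df) &&
      any(is.na(df$compound) | !nzchar(trimws(df$compound)))) {
    stop_kpuu("empty compound id in table")
  }
  df
}

#' @rdname load_compound_table
#' @param df A data frame previously produced by [load_compound_table()]
#'   or in the same layout.
#' @export
write_compound_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged validation tables
#'
#' The packaged 92-compound validation dataset: `kpuu_table2()` returns the
#' 30 marketed drugs with brain-binding fractions (homogenate and slice,
#' mean ± SD), in vitro 1-h and steady-state ratios, and in vivo unbound
#' ratios computed with each fu method; `kpuu_table3()` returns the 62
#' proprietary compounds (in vitro ratios and the slice-based in vivo
#' ratio; one compound appears twice as two independent determinations and
#' both rows are retained). `kpuu_pooled()` row-binds the shared columns of
#' both tables for the pooled 92-compound analysis.
#'
#' @return A data frame (30, 62 or 92 rows).
#' @examples
#' nrow(kpuu_table2())
#' nrow(kpuu_pooled())
#' @export
kpuu_table2 <- function() {
  load_compound_table(system.file("extdata", "table2_drugs.csv",
                                  package = "kpuu", mustWork = TRUE),
                      "table2")
}

#' @rdname kpuu_table2
#' @export
kpuu_table3 <- function() {
  load_compound_table(system.file("extdata", "table3_proprietary.csv",
                                  package = "kpuu", mustWork = TRUE),
                      "table3")
}

#' @rdname kpuu_table2
#' @export
kpuu_pooled <- function() {
  cols <- kpuu_schemas$table3
  rbind(cbind(kpuu_table2()[cols], source = "drugs"),
        cbind(kpuu_table3()[cols], source = "proprietary"))
}

#' Read or write a concentration profile CSV
#'
#' Two-column CSV (`time_min`, `conc_nM`) holding a free concentration-time
#' profile.
#'
#' @param path CSV path.
#' @param kind Profile kind (see [concentration_profile()]).
#' @return `load_profile()` returns a `"concentration_profile"`;
#'   `write_profile()` returns the path invisibly.
#' @export
load_profile <- function(path, kind = "plasma-free") {
  df <- load_compound_table(path, "profile")
  concentration_profile(df$time_min, df$conc_nm, kind = kind)
}

#' @rdname load_profile
#' @param profile A `"concentration_profile"`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "concentration_profile"))
  write.csv(data.frame(time_min = profile$times, conc_nM = profile$values),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration with method defaults
#'
#' Collects the method constants in one overridable place so variants are
#' auditable: slice water adhesion `V0` (0.106 mL/g), homogenate dilution
#' `D` (10), residual blood volume `V_vasc` (0.013 mL/g), sucrose
#' permeability threshold (5e-4 cm/min), concordance fold threshold `k`
#' (2), the transwell geometry, and an optional seed. The effective
#' configuration is echoed by batch outputs for provenance.
#'
#' @param V0,D,V_vasc,pe_threshold,fold_k Method constants (see above).
#' @param geometry A [transwell_geometry()].
#' @param seed Optional integer seed.
#' @return An object of class `"kpuu_config"`.
#' @examples
#' kpuu_config()
#' @export
kpuu_config <- function(V0 = 0.106, D = 10, V_vasc = 0.013,
                        pe_threshold = 5e-4, fold_k = 2,
                        geometry = transwell_geometry(), seed = NULL) {
  check_number(V0, "V0", 0, strict = TRUE)
  check_number(D, "D", 1)
  check_number(V_vasc, "V_vasc", 0)
  check_number(pe_threshold, "pe_threshold", 0)
  check_number(fold_k, "fold_k", 1)
  stopifnot(inherits(geometry, "transwell_geometry"))
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(V0 = V0, D = D, V_vasc = V_vasc,
                 pe_threshold = pe_threshold, fold_k = fold_k,
                 geometry = geometry, seed = seed),
            class = "kpuu_config")
}

#' @export
print.kpuu_config <- function(x, ...) {
  cat("kpuu configuration:\n")
  cat(sprintf("  V0 = %g mL/g, D = %g, V_vasc = %g mL/g\n", x$V0, x$D, x$V_vasc))
  cat(sprintf("  sucrose Pe threshold = %g cm/min, fold k = %g\n",
              x$pe_threshold, x$fold_k))
  cat("  "); print(x$geometry)
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

format_config <- function(config) {
  g <- config$geometry
  sprintf("V0=%g;D=%g;V_vasc=%g;pe_threshold=%g;fold_k=%g;V_lum=%g;V_ab=%g;A=%g",
          config$V0, config$D, config$V_vasc, config$pe_threshold,
          config$fold_k, g$V_lum, g$V_ab, g$A)
}

#' Batch transwell analysis of a measurement table
#'
#' Fits the steady-state extrapolation to every row of a transwell
#' measurement table (schema `"transwell"`), computes the 1-h ratio and the
#' sucrose integrity QC, and returns the table augmented with `R_1h`,
#' `R_ss`, `Pe`, `qc_pass` and a per-row `note`. Rows whose fit fails get
#' `NA` estimates and an explanatory note; QC failures are reported with a
#' message, never dropped silently. The effective configuration string is
#' attached as the `"config"` attribute of the result.
#'
#' @param df A data frame with columns `compound`, `c_d0`, `c_d_t`,
#'   `c_r_t`, `t_min`, `sucrose_frac` (as read by [load_compound_table()]).
#' @param config A [kpuu_config()].
#' @param drop_qc_failures Drop rows failing sucrose QC from the result
#'   (default `FALSE`; exclusions are always messaged). With every row
#'   failing QC, an error is raised rather than an empty result.
#' @return The augmented data frame.
#' @examples
#' tab <- data.frame(compound = "drug", c_d0 = 2, c_d_t = 1.6, c_r_t = 0.2,
#'                   t_min = 60, sucrose_frac = 0.05)
#' transwell_batch(tab)
#' @export
transwell_batch <- function(df, config = kpuu_config(),
                            drop_qc_failures = FALSE) {
  stopifnot(is.data.frame(df), inherits(config, "kpuu_config"))
  needed <- kpuu_schemas$transwell
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_kpuu(sprintf("schema error: missing column `%s`", missing[[1L]]))
  }
  n <- nrow(df)
  R_1h <- R_ss <- Pe <- rep(NA_real_, n)
  qc_pass <- rep(NA, n)
  note <- character(n)
  for (i in seq_len(n)) {
    m <- tryCatch(
      transwell_measurement(
        C_d0 = df$c_d0[i], C_d_t = df$c_d_t[i], C_r_t = df$c_r_t[i],
        t = df$t_min[i],
        sucrose_receiver_frac = if (is.na(df$sucrose_frac[i])) NA_real_
                                else df$sucrose_frac[i]),
      error = function(e) e)
    if (inherits(m, "error")) {
      note[i] <- conditionMessage(m)
      next
    }
    qc <- sucrose_qc(m, config$geometry, threshold = config$pe_threshold)
    Pe[i] <- qc$Pe
    qc_pass[i] <- qc$pass
    fit <- tryCatch(
      withCallingHandlers(
        transwell_fit(m, config$geometry),
        warning = function(w) {
          note[i] <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(fit, "error")) {
      note[i] <- conditionMessage(fit)
      next
    }
    cf <- coef(fit)
    R_1h[i] <- cf[["R_1h"]]
    R_ss[i] <- cf[["R_ss"]]
  }
  out <- cbind(df, R_1h = R_1h, R_ss = R_ss, Pe = Pe, qc_pass = qc_pass,
               note = note)
  failed <- which(!is.na(qc_pass) & !qc_pass)
  if (length(failed)) {
    message(sprintf("sucrose QC failed for %d of %d rows: %s",
                    length(failed), n,
                    paste(df$compound[failed], collapse = ", ")))
    if (drop_qc_failures) {
      out <- out[-failed, , drop = FALSE]
      if (nrow(out) == 0L) stop_kpuu("0 rows passed QC")
    }
  }
  attr(out, "config") <- format_config(config)
  out
}
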