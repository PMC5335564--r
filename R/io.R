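# Delimited-text input/output for dispersion data and reports.

#' Write dispersion data as TSV
#'
#' Columns `f_MHz`, `k_rad_per_mm`; `#` header comments carry the window
#' metadata so the file round-trips through [read_dispersion()].
#'
#' @param data A [dispersion_data()].
#' @param file Output path.
#' @export
write_dispersion <- function(data, file) {
  stopifnot(inherits(data, "dispersion_data"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# f_max = %.10g", data$f_max),
               sprintf("# k_max = %.10g", data$k_max),
               sprintf("# L = %.10g", data$L),
               "f_MHz\tk_rad_per_mm"), con)
  utils::write.table(data$points, con, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read dispersion data from TSV
#'
#' @param file Path written by [write_dispersion()] (or any two-column TSV
#'   of f and k with optional `# key = value` headers).
#' @param f_max,k_max,L Metadata overrides; defaults come from the header
#'   comments when present.
#' @return A [dispersion_data()].
#' @export
read_dispersion <- function(file, f_max = NULL, k_max = NULL, L = NULL) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\S+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  names(tab)[1:2] <- c("f", "k")
  if (is.null(f_max)) f_max <- meta$f_max %||% max(tab$f)
  if (is.null(k_max)) k_max <- meta$k_max %||% max(tab$k)
  if (is.null(L)) L <- meta$L %||% 20
  dispersion_data(tab, f_max = f_max, k_max = k_max, L = L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an inversion result as JSON
#'
#' Serializes the optimal parameters, pairing vector, objective value,
#' per-mode table and inlier indices.
#'
#' @param result An `inversion_result`.
#' @param file Output path.
#' @export
write_inversion_json <- function(result, file) {
  stopifnot(inherits(result, "inversion_result"))
  th <- result$theta
  out <- list(
    theta = list(h_s = th$h_s, r13 = th$r13, r33 = th$r33,
                 VL3 = th$VL3, VL1 = th$VL1, VT = th$VT),
    pairing = .canonical_mode_labels(length(result$pairing))[result$pairing],
    F = result$F_opt,
    inlier_percent = result$inlier_percent,
    per_mode = result$per_mode,
    inlier_index = which(result$assignments$inlier),
    seed = result$seed)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a Norm surface as a dense matrix file
#'
#' One row per frequency bin; `#` headers carry the wavenumber grid and the
#' testing-vector attenuation.
#'
#' @param surface A `norm_surface` from [norm_function()].
#' @param file Output path.
#' @export
write_norm_surface <- function(surface, file) {
  stopifnot(inherits(surface, "norm_surface"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# alpha = %.10g", surface$alpha),
               paste0("# k_grid = ",
                      paste(format(surface$k_grid, digits = 10),
                            collapse = "\t"))), con)
  tab <- cbind(f_MHz = surface$freqs, surface$values)
  utils::write.table(tab, con, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
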