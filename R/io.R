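## File formats: comma-separated UTF-8 with a mandatory header row and "."
## decimal separator; lines starting with '#' are metadata comments (every
## writer stamps version, seed and a config hash). FASTA via Biostrings.
## Run configuration files are flat "key: value" text.

output_header <- function(seed = NA, config = NULL) {
  h <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e8
  sprintf("# chemevol %s seed=%s config_hash=%08d",
          as.character(packageVersion("chemevol")),
          as.character(seed), h)
}

write_csv_with_header <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) abort("malformed CSV '%s': %s", path,
                                           conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort("CSV '%s' is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Read and write variant-fraction series
#'
#' CSV with columns `generation`, `fraction` and optional `depth`, `ci_low`,
#' `ci_high`; comment lines start with `#`.
#'
#' @param path File path.
#' @return `read_fraction_series()`: a [fraction_series()].
#' @export
read_fraction_series <- function(path) {
  df <- read_csv_checked(path, c("generation", "fraction"))
  opt <- function(col) if (col %in% names(df) && !all(is.na(df[[col]])))
    df[[col]] else NULL
  fraction_series(df$generation, df$fraction, depth = opt("depth"),
                  ci_low = opt("ci_low"), ci_high = opt("ci_high"))
}

#' @rdname read_fraction_series
#' @param fs A [fraction_series()].
#' @param seed,config Metadata stamped into the header comment.
#' @export
write_fraction_series <- function(fs, path, seed = NA, config = NULL) {
  stopifnot(inherits(fs, "fraction_series"))
  write_csv_with_header(as.data.frame(fs), path, seed, config)
}

#' Read and write simulated trajectories
#'
#' CSV with columns `time_h`, `S_mM`, then one biomass column per strain.
#'
#' @param path File path.
#' @return `read_trajectory()`: a `trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read_csv_checked(path, c("time_h", "S_mM"))
  strains <- setdiff(names(df), c("time_h", "S_mM"))
  if (!length(strains)) abort("trajectory CSV has no biomass columns")
  mat <- as.matrix(df[, c("S_mM", strains), drop = FALSE])
  new_trajectory(df$time_h, mat, strains)
}

#' @rdname read_trajectory
#' @param traj A `trajectory` from [simulate_chemostat()].
#' @param seed,config Metadata stamped into the header comment.
#' @export
write_trajectory <- function(traj, path, seed = NA, config = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  write_csv_with_header(as.data.frame(traj), path, seed, config)
}

#' Write site hits as BED-like delimited text
#'
#' Tab-separated columns `seq_id`, `start`, `end`, `strand`, `mismatches`,
#' `site_seq` with 0-based half-open coordinates.
#'
#' @param hits A `site_hits` frame from [scan_cre_sites()].
#' @param path File path.
#' @param seed,config Metadata stamped into the header comment.
#' @export
write_site_hits <- function(hits, path, seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  writeLines(paste(c("seq_id", "start", "end", "strand", "mismatches",
                     "site_seq"), collapse = "\t"), con)
  if (nrow(hits))
    writeLines(do.call(paste, c(as.list(as.data.frame(hits)), sep = "\t")),
               con)
  invisible(path)
}

#' Write a position frequency matrix as a 4xL delimited matrix
#'
#' @param pfm A [build_pfm()] result.
#' @param path File path.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pf_matrix"))
  df <- data.frame(base = rownames(pfm$counts), pfm$counts)
  names(df) <- c("base", paste0("pos", seq_len(ncol(pfm$counts))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write flat key-value run configuration
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path File path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      abort("malformed config line (expected 'key: value'): '%s'", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' Write a fit result as a flat key-value report plus covariance CSV
#'
#' @param fit A `fit_result` from [fit_washin()].
#' @param path Report path; the covariance goes to `<path>.cov.csv`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  kv <- c(as.list(fit$estimates),
          list(residual_sum = fit$residual_sum, n_obs = fit$n_obs,
               singular_covariance = tolower(as.character(fit$singular)),
               ratio_only = if (length(fit$identifiable_combos))
                 paste(fit$identifiable_combos, collapse = ";") else "none",
               convergence = fit$convergence))
  write_config(kv, path)
  write.csv(as.data.frame(fit$covariance), paste0(path, ".cov.csv"),
            row.names = TRUE)
  invisible(path)
}
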