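#' @importFrom rlang hash abort warn inform .data
#' @importFrom stats rnbinom runif setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods is
NULL

# Closed vocabulary of sampling environments, ordered from ice to depth.
ENVIRONMENTS <- c("interior_ice", "sea_ice_interface", "epipelagic",
                  "meso_bathypelagic")

LOCALIZATION_CLASSES <- c("none", "sp_only", "tmd_only", "both")

#' Default target Pfam accession (DUF3494 ice-binding domain)
#' @return Normalized accession string `"pfam11999"`.
#' @export
default_target_pfam <- function() "pfam11999"

#' Normalize a Pfam accession
#'
#' Maps any of `"PF11999.6"`, `"PF11999"`, `"Pfam11999"` or `"pfam11999"` to
#' the canonical lowercase form `"pfamNNNNN"` used throughout the package.
#'
#' @param acc Character vector of accessions.
#' @return Character vector of normalized accessions.
#' @export
#' @examples
#' normalize_pfam_acc(c("PF11999.6", "pfam16130"))
normalize_pfam_acc <- function(acc) {
  acc <- sub("\\.\\d+$", "", acc)
  out <- sub("^(PF|pf|Pfam|pfam)0*(\\d+)$", "\\2", acc)
  bad <- !grepl("^\\d+$", out)
  if (any(bad)) {
    abort(paste0("Cannot normalize Pfam accession(s): ",
                 paste(unique(acc[bad]), collapse = ", ")))
  }
  sprintf("pfam%05d", as.integer(out))
}

is_pfam_acc <- function(acc) grepl("^pfam\\d{5}$", acc)

#' @keywords internal
pct <- function(x, total = sum(x)) 100 * x / total

# Stable hash of a configuration object, recorded in output headers so a
# result table can always be traced to the exact parameter set that made it.
config_hash <- function(config) {
  substr(hash(config), 1L, 12L)
}

pkg_version <- function() {
  as.character(utils::packageVersion("ibparch"))
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline writers emit tab-separated tables preceded by a single
#' commented header line recording the package version and a hash of the
#' configuration that produced the table.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config Optional configuration object; hashed into the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ibparch %s\tconfig=%s", pkg_version(),
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path Path to a TSV written by this package.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(read.delim(path, comment.char = "#", sep = "\t",
                               stringsAsFactors = FALSE))
}

# read.delim wrapper for external TSVs with required-column validation.
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " table ", path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
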