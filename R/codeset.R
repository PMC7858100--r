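#' Read and validate a codeset definition
#'
#' A codeset assigns every probe on the panel a class (endogenous,
#' housekeeping, positive control, negative control) and, for the two MET
#' probes, a target role: \code{met_wt} for the probe counting canonical MET
#' transcripts and \code{met_dex14} for the probe spanning the exon 13-exon 15
#' junction of the skipped isoform.  Typical panels carry three housekeeping
#' genes (ACTB, PSMC4, MRPL19) plus the vendor's positive and negative
#' controls.
#'
#' @param path Path to a TSV or CSV file with columns \code{probe},
#'   \code{class} and \code{met_role}.  \code{class} must be one of
#'   \code{endogenous}, \code{housekeeping}, \code{positive_control},
#'   \code{negative_control}; \code{met_role} one of \code{met_wt},
#'   \code{met_dex14}, \code{none} (empty cells are read as \code{none}).
#' @return An object of class \code{met_codeset}: a data frame with columns
#'   \code{probe}, \code{class}, \code{met_role}, one row per probe.
#' @seealso [codeset()] to build the object directly from vectors.
#' @export
read_codeset <- function(path) {
  if (!file.exists(path)) stop("codeset file not found: ", path)
  df <- read_delim_auto(path)
  need <- c("probe", "class", "met_role")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("codeset file lacks column(s): ", paste(miss, collapse = ", "))
  role <- as.character(df$met_role)
  role[is.na(role) | role == ""] <- "none"
  codeset(probe = as.character(df$probe), class = as.character(df$class),
          met_role = role)
}

#' Construct a codeset from vectors
#'
#' @param probe Character vector of unique probe names.
#' @param class Probe class for each probe.
#' @param met_role MET target role for each probe (default \code{"none"}).
#' @return A validated \code{met_codeset} data frame.
#' @export
codeset <- function(probe, class, met_role = rep("none", length(probe))) {
  cs <- data.frame(probe = as.character(probe), class = as.character(class),
                   met_role = as.character(met_role),
                   stringsAsFactors = FALSE)
  validate_codeset(cs)
  class(cs) <- c("met_codeset", "data.frame")
  cs
}

PROBE_CLASSES <- c("endogenous", "housekeeping", "positive_control",
                   "negative_control")
MET_ROLES <- c("met_wt", "met_dex14", "none")

validate_codeset <- function(cs) {
  dup <- cs$probe[duplicated(cs$probe)]
  if (length(dup) > 0)
    stop("duplicate probe name(s) in codeset: ", paste(unique(dup), collapse = ", "))
  bad <- !(cs$class %in% PROBE_CLASSES)
  if (any(bad))
    stop("unknown probe class '", cs$class[which(bad)[1]], "' for probe '",
         cs$probe[which(bad)[1]], "'")
  badr <- !(cs$met_role %in% MET_ROLES)
  if (any(badr))
    stop("unknown met_role '", cs$met_role[which(badr)[1]], "' for probe '",
         cs$probe[which(badr)[1]], "'")
  n_wt <- sum(cs$met_role == "met_wt")
  n_dx <- sum(cs$met_role == "met_dex14")
  if (n_wt == 0) stop("missing MET wild-type probe (met_role = met_wt)")
  if (n_dx == 0) stop("missing METdelta-ex14 probe (met_role = met_dex14)")
  if (n_wt > 1) stop("multiple probes declared met_wt")
  if (n_dx > 1) stop("multiple probes declared met_dex14")
  if (sum(cs$class == "housekeeping") < 1)
    stop("codeset needs at least one housekeeping probe")
  invisible(cs)
}

# probe-name accessors used throughout the caller
cs_probes <- function(cs, class) cs$probe[cs$class == class]
cs_wt <- function(cs) cs$probe[cs$met_role == "met_wt"]
cs_dex14 <- function(cs) cs$probe[cs$met_role == "met_dex14"]

#' @export
print.met_codeset <- function(x, ...) {
  cat("Codeset with", nrow(x), "probes:",
      sum(x$class == "endogenous"), "endogenous,",
      sum(x$class == "housekeeping"), "housekeeping,",
      sum(x$class == "positive_control"), "positive control,",
      sum(x$class == "negative_control"), "negative control\n")
  cat("MET-wt probe:", cs_wt(x), "  METdelta-ex14 probe:", cs_dex14(x), "\n")
  invisible(x)
}

#' Write a codeset definition to a delimited file
#'
#' @param cs A \code{met_codeset}.
#' @param path Output path; extension picks the delimiter (.csv is
#'   comma-separated, anything else tab-separated).
#' @export
write_codeset <- function(cs, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(cs), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# delimiter sniffing: tab wins if present in the header, else comma
read_delim_auto <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}
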