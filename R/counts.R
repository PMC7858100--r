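#' Build a raw count container
#'
#' @param counts Non-negative integer matrix, samples in rows, probes in
#'   columns; rownames are sample ids, colnames probe names.
#' @param codeset The \code{met_codeset} the columns must match.
#' @param meta Optional per-sample annotation data frame (one row per sample,
#'   matched by a \code{sample_id} column or by rownames).  Conventional
#'   columns: \code{timepoint} (baseline/progression/unknown), \code{driver},
#'   plus one column per orthogonal assay holding positive/negative/unknown
#'   calls.
#' @return An object of class \code{met_counts}: list with elements
#'   \code{counts}, \code{codeset}, \code{meta}.
#' @export
met_counts <- function(counts, codeset, meta = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts matrix needs sample ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  missing_probe <- setdiff(codeset$probe, colnames(counts))
  if (length(missing_probe) > 0)
    stop("probe(s) in codeset but absent from counts: ",
         paste(missing_probe, collapse = ", "))
  extra <- setdiff(colnames(counts), codeset$probe)
  if (length(extra) > 0) {
    warning("dropping ", length(extra), " probe(s) not in codeset: ",
            paste(extra, collapse = ", "))
    counts <- counts[, codeset$probe, drop = FALSE]
  }
  counts <- counts[, codeset$probe, drop = FALSE]  # align to codeset order
  check_count_values(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    key <- if ("sample_id" %in% names(meta)) as.character(meta$sample_id)
           else rownames(meta)
    idx <- match(rownames(counts), key)
    meta <- meta[idx, setdiff(names(meta), "sample_id"), drop = FALSE]
    rownames(meta) <- rownames(counts)
  }
  structure(list(counts = counts, codeset = codeset, meta = meta),
            class = "met_counts")
}

check_count_values <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count (", counts[bad[1, 1], bad[1, 2]], ") for sample '",
         rownames(counts)[bad[1, 1]], "', probe '",
         colnames(counts)[bad[1, 2]], "': counts must be non-negative integers")
  invisible(counts)
}

#' @export
print.met_counts <- function(x, ...) {
  cat("Raw probe counts:", nrow(x$counts), "samples x", ncol(x$counts),
      "probes\n")
  if (!is.null(x$meta))
    cat("Sample annotations:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Read probe counts from RCC files or a delimited table
#'
#' Two dialects are supported.  \code{"rcc"} expects one nCounter RCC file per
#' sample and extracts the \code{Code_Summary} count section plus the sample
#' id (Sample Attributes ID, falling back to the file name); all other
#' instrument fields are ignored.  \code{"table"} expects a single delimited
#' file with sample ids in the first column and one column per probe.
#'
#' Every probe in the codeset must be present for every sample (a missing
#' probe is an error, never a silent zero); probes not in the codeset are
#' dropped with a warning.
#'
#' @param paths Character vector of file paths (length one for
#'   \code{dialect = "table"}).
#' @param codeset A \code{met_codeset}.
#' @param dialect \code{"rcc"} or \code{"table"}.
#' @param meta Optional annotation data frame, see [met_counts()].
#' @return A \code{met_counts} object with probes in codeset order.
#' @export
read_counts <- function(paths, codeset, dialect = c("table", "rcc"),
                        meta = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "table") {
    if (length(paths) != 1)
      stop("table dialect expects exactly one file")
    df <- read_delim_auto(paths)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric count column in ", paths)
    rownames(m) <- ids
  } else {
    rows <- lapply(paths, parse_rcc)
    ids <- vapply(rows, function(r) r$sample_id, "")
    probe_sets <- lapply(rows, function(r) r$counts$Name)
    all_probes <- Reduce(union, probe_sets)
    m <- matrix(NA_real_, length(rows), length(all_probes),
                dimnames = list(ids, all_probes))
    for (i in seq_along(rows))
      m[i, rows[[i]]$counts$Name] <- rows[[i]]$counts$Count
    if (anyNA(m[, intersect(colnames(m), codeset$probe), drop = FALSE])) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("probe '", colnames(m)[bad[2]], "' missing from RCC file of sample '",
           rownames(m)[bad[1]], "'")
    }
    m[is.na(m)] <- 0  # only possible for non-codeset probes, dropped below
  }
  met_counts(m, codeset, meta = meta)
}

# RCC files are ini-like CSV: <Tag> ... </Tag> sections; we use
# Sample_Attributes (ID) and Code_Summary (CodeClass,Name,Accession,Count).
parse_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- function(tag) {
    open <- grep(paste0("^<", tag, ">"), lines)
    close <- grep(paste0("^</", tag, ">"), lines)
    if (length(open) == 0 || length(close) == 0) return(NULL)
    lines[(open[1] + 1L):(close[1] - 1L)]
  }
  cs <- section("Code_Summary")
  if (is.null(cs))
    stop("no Code_Summary section in RCC file: ", path)
  con <- textConnection(cs)
  on.exit(close(con))
  tab <- utils::read.csv(con, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("Name", "Count") %in% names(tab)))
    stop("Code_Summary in ", path, " lacks Name/Count columns")
  sample_id <- NA_character_
  sa <- section("Sample_Attributes")
  if (!is.null(sa)) {
    kv <- strsplit(sa, ",")
    id_row <- which(vapply(kv, function(x) x[1] == "ID", TRUE))
    if (length(id_row) > 0 && length(kv[[id_row[1]]]) > 1)
      sample_id <- kv[[id_row[1]]][2]
  }
  if (is.na(sample_id) || sample_id == "")
    sample_id <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))
  list(sample_id = sample_id,
       counts = data.frame(Name = tab$Name, Count = as.numeric(tab$Count),
                           stringsAsFactors = FALSE))
}

#' Write a count matrix as a delimited table
#'
#' Companion writer for the \code{"table"} dialect of [read_counts()];
#' re-reading reproduces the matrix exactly.
#'
#' @param x A \code{met_counts} object or a counts matrix.
#' @param path Output path (.csv comma-separated, else tab).
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "met_counts")) x$counts else x
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one RCC file per sample
#'
#' Emits a minimal RCC (Header, Sample_Attributes with the sample id,
#' Lane_Attributes, Code_Summary) sufficient for [read_counts()] and for
#' vendor-style readers that only need the count section.
#'
#' @param x A \code{met_counts} object.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths.
#' @export
write_rcc <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- x$codeset
  cls_map <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
               positive_control = "Positive", negative_control = "Negative")
  paths <- character(nrow(x$counts))
  for (i in seq_len(nrow(x$counts))) {
    id <- rownames(x$counts)[i]
    p <- file.path(dir, paste0(id, ".RCC"))
    lines <- c(
      "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>", "",
      "<Sample_Attributes>", paste0("ID,", id), "Owner,", "Comments,",
      "Date,20200101", "GeneRLF,met_panel", "</Sample_Attributes>", "",
      "<Lane_Attributes>", paste0("ID,", ((i - 1L) %% 12L) + 1L),
      "FovCount,555", "FovCounted,540", "BindingDensity,0.5",
      "</Lane_Attributes>", "",
      "<Code_Summary>", "CodeClass,Name,Accession,Count",
      paste(cls_map[cs$class], cs$probe, paste0("REF_", cs$probe),
            x$counts[i, cs$probe], sep = ","),
      "</Code_Summary>")
    writeLines(lines, p)
    paths[i] <- p
  }
  invisible(paths)
}

#' Read per-sample annotations
#'
#' Annotations carry the orthogonal assay calls (RT-PCR, DNA/RNA NGS, FISH,
#' IHC tiers) and clinical grouping variables used for concordance and group
#' comparisons.  Wide format: one row per sample (column \code{sample_id}),
#' one column per field; empty cells and the literal \code{unknown} become
#' \code{NA} and are excluded pairwise from downstream denominators.
#'
#' @param path TSV/CSV path.
#' @return Data frame keyed by \code{sample_id}.
#' @export
read_annotations <- function(path) {
  df <- read_delim_auto(path)
  if (!"sample_id" %in% names(df))
    stop("annotations file needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotations")
  for (j in setdiff(names(df), "sample_id")) {
    v <- df[[j]]
    if (is.character(v)) v[v %in% c("", "unknown", "NA")] <- NA
    df[[j]] <- v
  }
  df
}
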