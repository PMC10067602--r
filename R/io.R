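#' Read a gene-expression matrix
#'
#' Reads a delimited text file (TSV by default, CSV by extension or `sep`)
#' with one header row into a genes-by-samples numeric matrix. Gene and
#' sample identifiers are trimmed of surrounding whitespace and matched
#' case-sensitively; no alias resolution is attempted. Duplicate gene rows
#' are collapsed by their mean with a warning; duplicate sample columns are
#' an error. Any missing or non-numeric cell is a load error naming the
#' offending row and column.
#'
#' @param path Path to the file.
#' @param orientation `"genes_rows"` (default) if rows are genes, or
#'   `"samples_rows"` if rows are samples (the matrix is transposed after
#'   reading so that the result is always genes x samples).
#' @param sep Field separator; `NULL` (default) chooses `","` for `.csv`
#'   files and tab otherwise.
#' @return A numeric matrix, genes in rows, samples in columns, with unique
#'   dimnames and no non-finite values.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs an id column plus at least one value column")
  ids <- trimws(raw[[1L]])
  cols <- trimws(colnames(raw)[-1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing expression value at row '%s', column '%s' (cell value '%s')",
                 ids[bad[1L, 1L]], cols[bad[1L, 2L]], vals[bad[1L, 1L], bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, cols)
  if (orientation == "samples_rows") num <- t(num)
  if (anyDuplicated(colnames(num))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(num))) {
    dup <- unique(rownames(num)[duplicated(rownames(num))])
    warning(sprintf("collapsed %d duplicated gene id(s) by mean: %s",
                    length(dup), paste(head(dup, 5L), collapse = ", ")))
    num <- rowsum(num, group = rownames(num), reorder = FALSE) /
      as.vector(table(factor(rownames(num), levels = unique(rownames(num)))))
  }
  num
}

#' Read clinical follow-up records
#'
#' Reads a delimited table with a sample identifier, an overall-survival
#' time and an event indicator; any remaining columns are kept as
#' covariates. Rows whose time or event is missing (or whose event value is
#' not covered by `event_map`) are dropped and the count is reported with a
#' message, mirroring the usual cohort rule that patients without survival
#' information are removed.
#'
#' @param path Path to the file.
#' @param sep Field separator (`NULL`: by extension, as [read_expression()]).
#' @param id_col,time_col,event_col Column names; `NULL` (default)
#'   auto-detects from common headings (`sample`/`id`, `time`/`os_time`/
#'   `futime`, `event`/`status`).
#' @param event_map Named numeric vector mapping event codes to 0/1. The
#'   default accepts 0/1 codings; pass e.g. `c(dead = 1, alive = 0)` for
#'   textual codes.
#' @return A data frame with columns `sample`, `time`, `event` and any
#'   covariates, with attribute `n_dropped` giving the dropped-row count.
#' @export
read_clinical <- function(path, sep = NULL, id_col = NULL, time_col = NULL,
                          event_col = NULL, event_map = c("0" = 0, "1" = 1)) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  nm <- trimws(colnames(raw))
  colnames(raw) <- nm
  pick <- function(given, patterns, what) {
    if (!is.null(given)) {
      if (!given %in% nm) stop(sprintf("column '%s' not found", given))
      return(given)
    }
    hit <- nm[grepl(patterns, nm, ignore.case = TRUE)]
    if (length(hit) == 0L) stop(sprintf("no %s column identifiable in: %s",
                                        what, paste(nm, collapse = ", ")))
    hit[1L]
  }
  id_col <- if (is.null(id_col)) {
    hit <- nm[grepl("^(sample([._ ]?id)?|patient([._ ]?id)?|id|barcode)$", nm, ignore.case = TRUE)]
    if (length(hit) > 0L) hit[1L] else nm[1L]
  } else pick(id_col, NULL, "sample id")
  time_col <- pick(time_col, "^(os[._ ]?time|time|os|survival[._ ]?time|futime|follow[._ ]?up)$", "survival time")
  event_col <- pick(event_col, "^(os[._ ]?event|event|status|os[._ ]?status|vital[._ ]?status|censor(ed)?)$", "event")

  samp <- trimws(as.character(raw[[id_col]]))
  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  ev_raw <- trimws(as.character(raw[[event_col]]))
  event <- unname(event_map[ev_raw])
  unknown <- !is.na(ev_raw) & ev_raw != "" & !(ev_raw %in% names(event_map))
  if (any(unknown)) {
    stop("event values not covered by event_map: ",
         paste(unique(ev_raw[unknown]), collapse = ", "))
  }
  keep <- !is.na(time) & !is.na(event)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) message(sprintf("dropped %d record(s) without survival information", n_dropped))
  time <- time[keep]; event <- event[keep]; samp <- samp[keep]
  if (any(time < 0)) stop("negative survival time for sample(s): ",
                          paste(samp[time < 0], collapse = ", "))
  if (!all(event %in% c(0, 1))) stop("event_map must map onto {0, 1}")
  out <- data.frame(sample = samp, time = time, event = event,
                    stringsAsFactors = FALSE)
  extra <- setdiff(nm, c(id_col, time_col, event_col))
  for (cn in extra) out[[cn]] <- raw[[cn]][keep]
  attr(out, "n_dropped") <- n_dropped
  out
}

# Conventional nonsynonymous variant classes (MAF vocabulary).
maf_nonsynonymous <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
  "Nonstop_Mutation", "Translation_Start_Site"
)

maf_known_classes <- c(
  maf_nonsynonymous,
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA",
  "Targeted_Region"
)

#' Read a MAF-lite mutation table
#'
#' Minimal MAF reader: a TSV with `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns (extras ignored). Unknown variant
#' classes are kept with a warning. An empty table is valid.
#'
#' @param path Path to the file.
#' @return A data frame with columns `sample`, `gene`,
#'   `variant_classification`.
#' @export
read_maf_lite <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols) > 0L) {
    stop("MAF-lite file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(sample = trimws(raw$Tumor_Sample_Barcode),
                    gene = trimws(raw$Hugo_Symbol),
                    variant_classification = trimws(raw$Variant_Classification),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$variant_classification), maf_known_classes)
  if (length(unknown) > 0L) {
    warning("unknown variant classification(s) kept: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Genes within a set are de-duplicated; duplicate set
#' names are an error.
#'
#' @param path Path to the file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, function(p) trimws(p[1L]), character(1))
  if (anyDuplicated(nm)) stop("duplicate gene-set names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    genes <- unique(trimws(p[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("gene set '%s' is empty", trimws(p[1L])))
    genes
  })
  names(sets) <- nm
  sets
}

#' Serialize / deserialize a pair risk model
#'
#' Models are stored as JSON with a `schema_version` field. Coefficients
#' and the cutoff are written as full-precision decimal strings and parsed
#' back to doubles exactly once, so a write/read round-trip reproduces the
#' model bit-exactly on any platform.
#'
#' @param model An object of class `mkpc` (see [mkpc()], [published_mkpc()]).
#' @param path Output (input) path.
#' @return `read_model` returns the reconstructed `mkpc` object;
#'   `write_model` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mkpc"))
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    schema_version = 1L,
    terms = lapply(seq_len(nrow(model$terms)), function(i) {
      list(gene_a = model$terms$gene_a[i],
           gene_b = model$terms$gene_b[i],
           coefficient = num(model$terms$coefficient[i]))
    }),
    cutoff = num(model$cutoff),
    metadata = model$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version)) stop("not a pair risk model file: no schema_version")
  terms <- data.frame(
    gene_a = vapply(obj$terms, function(t) t$gene_a, character(1)),
    gene_b = vapply(obj$terms, function(t) t$gene_b, character(1)),
    coefficient = vapply(obj$terms, function(t) as.numeric(t$coefficient), numeric(1)),
    stringsAsFactors = FALSE
  )
  new_mkpc(terms = terms, cutoff = as.numeric(obj$cutoff),
           metadata = lapply(obj$metadata, identity))
}
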