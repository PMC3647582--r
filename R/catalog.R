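#' Load a TRAV/TRBV interface-polymorphism catalog
#'
#' Reads a TSV of nonsynonymous germline variants in the TCR V-gene regions
#' that contact the peptide-MHC surface (N-terminus, CDR1, CDR2, HV4;
#' IMGT residue numbering; CDR2 taken with one extra N-terminal residue to
#' cover its pMHC contact, recorded as part of the region definition, not a
#' renumbering). Expected header: \code{chain} (alpha/beta), \code{region},
#' \code{position}, \code{substitution} ("from/to" one-letter codes),
#' \code{genes} (semicolon-separated) and \code{provenance}.
#'
#' A packaged transcription of the published compilation ships at
#' \code{system.file("extdata", "table2_polymorphisms.tsv",
#' package = "stratpower")}.
#'
#' @param path TSV file path; defaults to the packaged catalog.
#' @param strict if \code{TRUE} (default), any malformed row aborts with
#'   the offending line numbers; if \code{FALSE}, malformed rows are
#'   reported in a warning and skipped.
#' @return A data frame of validated records (one row per substitution
#'   record; \code{genes} kept as a semicolon-separated string).
#' @examples
#' cat22 <- load_catalog()
#' count_distinct_positions(cat22)  # 19
#' @export
load_catalog <- function(path = system.file("extdata",
                                            "table2_polymorphisms.tsv",
                                            package = "stratpower"),
                         strict = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain", "region", "position", "substitution", "genes",
            "provenance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("empty catalog file: ", path)
    df$position <- integer(0)
    return(df[need])
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos_num <- suppressWarnings(as.numeric(df$position))
  sub_parts <- strsplit(df$substitution, "/", fixed = TRUE)
  sub_ok <- vapply(sub_parts, function(s)
    length(s) == 2L && all(s %in% aa), logical(1))
  gene_lists <- strsplit(df$genes, ";", fixed = TRUE)
  gene_lists <- lapply(gene_lists, trimws)
  genes_ok <- vapply(gene_lists, function(g)
    length(g) >= 1L && all(grepl("^TR[AB]V", g)), logical(1))
  chain_ok <- df$chain %in% c("alpha", "beta") &
    mapply(function(ch, g) {
      pre <- if (identical(ch, "alpha")) "^TRAV" else "^TRBV"
      all(grepl(pre, g))
    }, df$chain, gene_lists)
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad))
      problems <<- c(problems,
                     paste0(what, " at line(s) ",
                            paste(which(bad) + 1L, collapse = ", ")))
    bad
  }
  bad <- flag(!df$region %in% c("N-term", "CDR1", "CDR2", "HV4"),
              "unknown region")
  bad <- bad | flag(is.na(pos_num) | pos_num < 1 |
                      abs(pos_num - round(pos_num)) > 0, "bad position")
  bad <- bad | flag(!sub_ok, "bad substitution")
  bad <- bad | flag(!genes_ok, "bad gene list")
  bad <- bad | flag(!chain_ok, "chain/gene mismatch")
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) stop("malformed catalog rows: ", msg, call. = FALSE)
    warning("skipping malformed catalog rows: ", msg)
    df <- df[!bad, , drop = FALSE]
    pos_num <- pos_num[!bad]
  }
  df$position <- as.integer(pos_num)
  df$genes <- vapply(strsplit(df$genes, ";", fixed = TRUE),
                     function(g) paste(trimws(g), collapse = ";"),
                     character(1))
  rownames(df) <- NULL
  df[need]
}

catalog_gene_vector <- function(records) {
  unlist(strsplit(records$genes, ";", fixed = TRUE), use.names = FALSE)
}

#' Count distinct polymorphic positions
#'
#' Distinct (chain, region, IMGT position) triples across the records;
#' multiple substitutions at one position count once.
#'
#' @param records a catalog data frame from \code{\link{load_catalog}}.
#' @return Integer count.
#' @export
count_distinct_positions <- function(records) {
  if (nrow(records) == 0L) return(0L)
  length(unique(paste(records$chain, records$region, records$position,
                      sep = "|")))
}

#' Count distinct genes
#'
#' Distinct gene names pooled over all records' gene lists.
#'
#' @inheritParams count_distinct_positions
#' @return Integer count.
#' @export
count_distinct_genes <- function(records) {
  if (nrow(records) == 0L) return(0L)
  length(unique(catalog_gene_vector(records)))
}

#' Per-region catalog breakdown
#'
#' @inheritParams count_distinct_positions
#' @return A data frame with one row per (chain, region): number of
#'   substitution records, distinct positions and distinct genes.
#' @export
catalog_breakdown <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(chain = character(0), region = character(0),
                      substitutions = integer(0), positions = integer(0),
                      genes = integer(0)))
  keys <- unique(records[c("chain", "region")])
  keys <- keys[order(keys$chain, keys$region), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$chain == keys$chain[i] &
                     records$region == keys$region[i], , drop = FALSE]
    data.frame(chain = keys$chain[i], region = keys$region[i],
               substitutions = nrow(sub),
               positions = count_distinct_positions(sub),
               genes = count_distinct_genes(sub))
  }))
  rownames(out) <- NULL
  out
}
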