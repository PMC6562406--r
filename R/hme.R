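# Histone-modifying-enzyme annotation: a curated catalogue of 88 known or
# putative HMEs (17 acetyltransferases, 18 deacetylases, 32 methyltransferases,
# 21 demethylases) with substrate residues, plus class counts and a
# writer/eraser consistency report against measured mark changes.

.HME_CLASSES <- c("acetyltransferase", "deacetylase", "methyltransferase",
                  "demethylase")

# substrate tokens look like H3K9, H4K20, H3R2
.SUBSTRATE_RE <- "^H[1-4](K|R)[0-9]+$"

#' Load the histone-modifying-enzyme catalogue
#'
#' The packaged catalogue is curated from the literature to cover the four
#' enzyme classes at their reported sizes; exact membership at the margins
#' (putative enzymes) is a curation choice, and the file can be replaced by a
#' user-supplied TSV of the same schema (`symbol`, `class`, `substrates`
#' comma-separated, `notes`).
#'
#' @param path TSV path; `NULL` (default) loads the packaged catalogue.
#' @return data.frame `symbol`, `class`, `substrates`, `notes`, validated.
#' @export
load_hme_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hme_catalog_curated.tsv",
                        package = "histonePTM", mustWork = TRUE)
  }
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "class", "substrates") %in% names(cat_df)))
  bad <- setdiff(unique(cat_df$class), .HME_CLASSES)
  if (length(bad) > 0) stop("unknown enzyme class(es): ",
                            paste(bad, collapse = ", "))
  if (anyDuplicated(cat_df$symbol)) stop("duplicate enzyme symbols")
  toks <- unlist(strsplit(cat_df$substrates, ",", fixed = TRUE))
  badtok <- toks[!grepl(.SUBSTRATE_RE, toks)]
  if (length(badtok) > 0) stop("malformed substrate token(s): ",
                               paste(unique(badtok), collapse = ", "))
  cat_df
}

#' Enzyme counts per class
#'
#' @param catalog data.frame from [load_hme_catalog()].
#' @return Named list: one count per class plus `total`.
#' @export
hme_class_counts <- function(catalog) {
  counts <- lapply(.HME_CLASSES, function(cl) sum(catalog$class == cl))
  names(counts) <- .HME_CLASSES
  counts$total <- nrow(catalog)
  counts
}

# "H3K9me3" / "H3K14ac" -> list(residue = "H3K9", type = "me"/"ac")
.parse_mark <- function(mark) {
  m <- regmatches(mark, regexec("^(H[1-4][KR][0-9]+)(me[123]?|ac)$", mark))[[1]]
  if (length(m) == 0) stop("cannot parse mark '", mark,
                           "' as histone residue + me/ac")
  list(residue = m[2], type = substr(m[3], 1, 2))
}

#' Writer/eraser consistency report for measured mark changes
#'
#' For each measured mark (e.g. `H3K9me3` increased in tumor), lists the
#' catalogue enzymes acting on that residue with the matching chemistry
#' (methyltransferases/demethylases for methyl marks, acetyltransferases/
#' deacetylases for acetyl marks) and checks whether their expression change
#' predicts the mark's direction: an upregulated writer predicts an increased
#' mark, an upregulated eraser a decreased mark.
#'
#' @param mark_changes data.frame `mark` (e.g. `"H3K14ac"`), `direction`
#'   (`"increase"`/`"decrease"`).
#' @param catalog data.frame from [load_hme_catalog()].
#' @param expression_changes data.frame `symbol`, `log2fc` (enzyme
#'   differential expression, e.g. exported from an external RNA-seq
#'   analysis).
#' @return List: `report` (data.frame `mark`, `symbol`, `role`,
#'   `enzyme_direction`, `concordant`) and `unmatched` (expression symbols
#'   absent from the catalogue).
#' @export
hme_consistency_report <- function(mark_changes, catalog,
                                   expression_changes) {
  stopifnot(all(c("mark", "direction") %in% names(mark_changes)),
            all(c("symbol", "log2fc") %in% names(expression_changes)))
  unmatched <- setdiff(expression_changes$symbol, catalog$symbol)
  rows <- list()
  subs <- strsplit(catalog$substrates, ",", fixed = TRUE)
  for (i in seq_len(nrow(mark_changes))) {
    mk <- .parse_mark(mark_changes$mark[i])
    mark_up <- mark_changes$direction[i] == "increase"
    writer_cl <- if (mk$type == "me") "methyltransferase" else "acetyltransferase"
    eraser_cl <- if (mk$type == "me") "demethylase" else "deacetylase"
    hits <- which(vapply(subs, function(s) mk$residue %in% s, TRUE) &
                    catalog$class %in% c(writer_cl, eraser_cl))
    for (j in hits) {
      e <- match(catalog$symbol[j], expression_changes$symbol)
      if (is.na(e)) next
      enz_up <- expression_changes$log2fc[e] > 0
      role <- if (catalog$class[j] == writer_cl) "writer" else "eraser"
      concordant <- if (role == "writer") enz_up == mark_up else
        enz_up != mark_up
      rows[[length(rows) + 1L]] <- data.frame(
        mark = mark_changes$mark[i], symbol = catalog$symbol[j], role = role,
        enzyme_direction = if (enz_up) "up" else "down",
        concordant = concordant, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mark = character(0), symbol = character(0),
               role = character(0), enzyme_direction = character(0),
               concordant = logical(0), stringsAsFactors = FALSE)
  list(report = report, unmatched = unmatched)
}
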