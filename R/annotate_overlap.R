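# ROH-gene interval overlap and keyword triage of enrichment-term tables.

#' Genes overlapping ROH segments
#'
#' Assigns a gene to a segment when their intervals intersect in at least
#' one base pair (both in 1-based inclusive coordinates, as produced by
#' [detect_roh()] and [read_gene_bed()]).  Set `mode = "contained"` to
#' require the gene to lie entirely inside the segment.
#'
#' @param segments a data.table of ROH segments with columns `chrom`,
#'   `start_bp`, `end_bp` (extra columns are carried through).
#' @param genes a data.table of gene intervals with columns `chrom`,
#'   `start`, `end`, `gene`.
#' @param mode `"any"` (>= 1 bp overlap, default) or `"contained"`.
#' @return a list with `per_segment` (one row per segment-gene pair:
#'   segment columns plus `gene`) and `genes` (sorted, deduplicated union
#'   of overlapped gene names).
#' @export
overlap_genes <- function(segments, genes, mode = c("any", "contained")) {
  mode <- match.arg(mode)
  segs <- as.data.table(segments)
  gn <- as.data.table(genes)
  if (nrow(segs) == 0L || nrow(gn) == 0L) {
    return(list(per_segment = cbind(segs[0], gene = character(0)),
                genes = character(0)))
  }
  q <- copy(gn)[, `:=`(qstart = start, qend = end)]
  s <- copy(segs)[, `:=`(start = start_bp, end = end_bp)]
  setkey(s, chrom, start, end)
  ov <- foverlaps(q, s, by.x = c("chrom", "qstart", "qend"),
                  by.y = c("chrom", "start", "end"), nomatch = NULL)
  if (mode == "contained") {
    ov <- ov[qstart >= start_bp & qend <= end_bp]
  }
  seg_cols <- names(segs)
  per_segment <- ov[, c(seg_cols, "gene"), with = FALSE]
  setorderv(per_segment, intersect(c("sample_id", "chrom", "start_bp", "gene"),
                                   names(per_segment)))
  list(per_segment = per_segment[],
       genes = sort(unique(per_segment$gene)))
}

#' Read an enrichment-term table
#'
#' Tab-separated export of a gene-list enrichment analysis: columns
#' category, term, score, comma-joined gene names.
#'
#' @param path path to the table.
#' @return a data.table with columns `category`, `term`, `score`
#'   (numeric, NA allowed) and `genes` (list column of gene names).
#' @export
read_enrichment_table <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", quote = "",
              colClasses = "character")
  if (ncol(dt) < 4L) {
    abort_arg("enrichment table needs 4 columns (category, term, score, genes)")
  }
  setnames(dt, 1:4, c("category", "term", "score", "genes"))
  if (dt$category[1L] %in% c("category", "Category")) dt <- dt[-1L]
  enrichment_table(category = dt$category, term = dt$term,
                   score = suppressWarnings(as.numeric(dt$score)),
                   genes = strsplit(dt$genes, ",", fixed = TRUE))
}

#' Construct an enrichment-term table
#'
#' @param category category labels (e.g. "Biological Process",
#'   "Mouse Phenotype", "Disease", "PubMed").
#' @param term term names (non-empty).
#' @param score optional numeric scores.
#' @param genes list of character vectors of gene names per term.
#' @return a data.table with a `genes` list column.
#' @export
enrichment_table <- function(category, term, score = NA_real_, genes) {
  if (any(!nzchar(term))) abort_arg("terms must be non-empty")
  data.table(category = as.character(category), term = as.character(term),
             score = as.numeric(score), genes = as.list(genes))
}

#' Keyword triage of enrichment terms
#'
#' Retains rows whose term contains any keyword as a case-insensitive
#' substring, and reports per-category counts plus the deduplicated union
#' of genes across retained rows.  Only term names are searched, not gene
#' names.
#'
#' @param rows an [enrichment_table()].
#' @param keywords non-empty character vector of keywords; the
#'   "hermaphroditism/hermaphroditic" pair is naturally expressed as the
#'   single stem "hermaphrodit".
#' @return a list with `rows` (retained), `counts` (named integer vector
#'   per category present in the input) and `genes` (sorted union).
#' @export
#' @examples
#' tab <- enrichment_table(category = "Disease",
#'                         term = "true hermaphroditism",
#'                         genes = list(c("RSPO1", "SOX9")))
#' keyword_triage(tab, c("Development", "Sex", "hermaphrodit"))$counts
keyword_triage <- function(rows,
                           keywords = c("Development", "Sex", "hermaphrodit")) {
  if (length(keywords) == 0L || any(!nzchar(keywords))) {
    abort_arg("keywords must be non-empty strings")
  }
  term_lc <- tolower(rows$term)
  hit <- rep(FALSE, nrow(rows))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, term_lc, fixed = TRUE)
  }
  kept <- rows[hit]
  cats <- unique(rows$category)
  counts <- vapply(cats, function(cc) sum(kept$category == cc), integer(1))
  list(rows = kept,
       counts = setNames(counts, cats),
       genes = sort(unique(unlist(kept$genes))))
}

#' Drop unrecognized gene names by pattern
#'
#' Enrichment portals typically skip non-coding families such as miRNAs
#' and olfactory receptor genes; this filter reproduces that drop with
#' regular-expression exclusion patterns.
#'
#' @param genes character vector of gene names.
#' @param patterns regular expressions; matching names are removed.  The
#'   defaults target miRNA-style ("MIR...") and olfactory-receptor-style
#'   ("OR<digit>...") symbols.
#' @return the filtered gene vector.
#' @export
exclude_gene_patterns <- function(genes,
                                  patterns = c("^MIR[0-9]", "^OR[0-9]")) {
  if (length(patterns) == 0L) return(genes)
  drop <- Reduce(`|`, lapply(patterns, grepl, x = genes, ignore.case = TRUE))
  genes[!drop]
}
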