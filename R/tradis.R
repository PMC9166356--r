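# Transposon-insertion-sequencing (TraDIS) essentiality calling.
#
# Pipeline: curate insertions (drop the first 5% and last 20% of each CDS,
# strand-aware), compute the insertion index log2(IPKMc + 1) per gene, anchor
# percentile thresholds on a reference essential-gene set, and classify.
#
# Insertion positions are 1-based genomic bp; CDS annotations are 1-based
# inclusive with strand + or -. The relative coding position f of an
# insertion is measured from the translational start: on the + strand
# f = (pos - start + 1) / L, on the - strand f = (end - pos + 1) / L.
# "First 5%" is f in (0, 0.05] (discarded), "last 20%" is f in (0.80, 1]
# (discarded); retained insertions satisfy 0.05 < f <= 0.80.

#' Construct an insertion dataset
#'
#' @param insertions data.frame with columns `replicon`, `position` (1-based
#'   bp) and `count` (reads or unique-insertion weight).
#' @param annotations data.frame with columns `gene_id`, `replicon`, `start`,
#'   `end` (1-based inclusive) and `strand` (`"+"`/`"-"`).
#' @param condition condition label.
#' @return list of class `insertion_dataset` with `total_insertions` equal to
#'   the sum of counts.
#' @export
insertion_dataset <- function(insertions, annotations, condition = "") {
  stopifnot(all(c("replicon", "position", "count") %in% names(insertions)),
            all(c("gene_id", "replicon", "start", "end", "strand") %in%
                  names(annotations)))
  if (any(insertions$position < 1)) stop("insertion positions must be >= 1")
  if (any(insertions$count < 0)) stop("insertion counts must be >= 0")
  if (any(annotations$start > annotations$end)) {
    stop("annotation with start > end: ",
         annotations$gene_id[annotations$start > annotations$end][1])
  }
  structure(list(condition = condition, insertions = insertions,
                 annotations = annotations,
                 total_insertions = sum(insertions$count)),
            class = "insertion_dataset")
}

#' Read insertion and annotation TSV files
#'
#' Insertions TSV: columns `replicon`, `position`, `count`. Annotation TSV:
#' columns `gene_id`, `replicon`, `start`, `end`, `strand`.
#'
#' @param insertions_path,annotation_path file paths.
#' @param condition condition label.
#' @return an `insertion_dataset`.
#' @export
read_insertion_tsv <- function(insertions_path, annotation_path, condition = "") {
  ins <- utils::read.delim(insertions_path, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  insertion_dataset(ins, ann, condition)
}

# relative coding position of insertion positions within one CDS (strand-aware)
.relative_position <- function(pos, start, end, strand) {
  L <- end - start + 1
  if (strand == "+") (pos - start + 1) / L else (end - pos + 1) / L
}

#' Curate insertions by coding position
#'
#' Discards insertions mapping within the first 5% (5'-end) or the last 20%
#' (3'-end) of any CDS, measured from the translational start on the coding
#' strand. Insertions outside every CDS are untouched. Boundary convention:
#' an insertion exactly at f = 0.05 lies in the discarded 5' window; one at
#' f = 0.80 is retained.
#'
#' @param dataset an `insertion_dataset`.
#' @param head_frac,tail_frac discarded 5' and 3' fractions.
#' @return a curated `insertion_dataset` (total recomputed).
#' @export
curate_insertions <- function(dataset, head_frac = 0.05, tail_frac = 0.20) {
  ins <- dataset$insertions
  ann <- dataset$annotations
  unknown <- setdiff(unique(ins$replicon), unique(ann$replicon))
  if (length(unknown) > 0) {
    warning("insertions on replicon(s) without annotation retained as ",
            "intergenic: ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(ins))
  for (g in seq_len(nrow(ann))) {
    a <- ann[g, ]
    idx <- which(ins$replicon == a$replicon &
                   ins$position >= a$start & ins$position <= a$end)
    if (length(idx) == 0) next
    f <- .relative_position(ins$position[idx], a$start, a$end, a$strand)
    keep[idx[f <= head_frac | f > 1 - tail_frac]] <- FALSE
  }
  insertion_dataset(ins[keep, , drop = FALSE], ann, dataset$condition)
}

#' Compute per-gene insertion indexes
#'
#' IPKM is insertions per kilobase of CDS per million library insertions:
#' `IPKM_g = (I_g / L_g[kb]) / (T / 1e6)` with `I_g` the insertion count in
#' gene g and `T` the library total. The insertion index is
#' `log2(IPKMc + 1)` computed on the curated counts. The library total `T`
#' may be taken from the uncurated library (default) or from the curated one
#' via `total`.
#'
#' @param dataset an `insertion_dataset` (uncurated).
#' @param curated logical; apply the 5%/20% curation before counting.
#' @param total `"raw"` to normalize by the uncurated library total,
#'   `"curated"` to normalize by the post-curation total.
#' @return data.frame with columns `gene_id`, `ipkm`, `ipkmc`, `index`.
#' @export
compute_insertion_index <- function(dataset, curated = TRUE,
                                    total = c("raw", "curated")) {
  total <- match.arg(total)
  if (dataset$total_insertions <= 0) stop("library has no insertions")
  ann <- dataset$annotations
  if (any(ann$end - ann$start + 1 <= 0)) stop("zero-length gene in annotation")
  cur <- if (curated) curate_insertions(dataset) else dataset
  T_raw <- dataset$total_insertions
  T_cur <- cur$total_insertions
  per_gene <- function(ds, Tlib) {
    vapply(seq_len(nrow(ann)), function(g) {
      a <- ann[g, ]
      idx <- ds$insertions$replicon == a$replicon &
        ds$insertions$position >= a$start & ds$insertions$position <= a$end
      I <- sum(ds$insertions$count[idx])
      Lkb <- (a$end - a$start + 1) / 1000
      (I / Lkb) / (Tlib / 1e6)
    }, numeric(1))
  }
  Tipkm <- T_raw
  Tipkmc <- if (total == "raw") T_raw else T_cur
  data.frame(
    gene_id = ann$gene_id,
    ipkm = per_gene(dataset, Tipkm),
    ipkmc = per_gene(cur, Tipkmc),
    index = log2(per_gene(cur, Tipkmc) + 1),
    stringsAsFactors = FALSE
  )
}

#' Derive essentiality thresholds from a reference essential set
#'
#' The lower (essential) threshold is the 65th percentile and the upper
#' (non-essential) threshold the 75th percentile of the insertion-index
#' distribution of a trusted reference essential-gene set
#' (linear-interpolation percentiles).
#'
#' @param reference_essential_indexes insertion-index values of the reference
#'   essential genes (at least 20).
#' @param lower_pct,upper_pct percentiles used for the two thresholds.
#' @return list of class `essentiality_thresholds` with `lower` and `upper`.
#' @export
derive_thresholds <- function(reference_essential_indexes,
                              lower_pct = 0.65, upper_pct = 0.75) {
  x <- reference_essential_indexes
  if (length(x) < 20) {
    stop("need >= 20 reference index values for stable percentiles, got ",
         length(x))
  }
  lower <- unname(stats::quantile(x, lower_pct, type = 7))
  upper <- unname(stats::quantile(x, upper_pct, type = 7))
  if (!(lower < upper)) {
    stop("degenerate thresholds (lower >= upper): reference distribution ",
         "too concentrated")
  }
  structure(list(lower = lower, upper = upper),
            class = "essentiality_thresholds")
}

#' Classify genes by insertion index
#'
#' `index <= lower` is essential; `index >= upper` non-essential; values in
#' between are unclassified. Genes in the low-coverage exclusion set are
#' reported as `excluded_low_coverage` regardless of index.
#'
#' @param records data.frame from [compute_insertion_index()].
#' @param thresholds an `essentiality_thresholds` object.
#' @param coverage_excluded character vector of gene ids to exclude.
#' @return `records` with an added `call` column.
#' @export
classify_genes <- function(records, thresholds, coverage_excluded = character(0)) {
  stopifnot(inherits(thresholds, "essentiality_thresholds"))
  call <- ifelse(records$index <= thresholds$lower, "essential",
                 ifelse(records$index >= thresholds$upper, "non_essential",
                        "unclassified"))
  call[records$gene_id %in% coverage_excluded] <- "excluded_low_coverage"
  records$call <- call
  records
}

#' TraDIS calling pipeline
#'
#' Runs curation, insertion-index computation, reference-anchored threshold
#' derivation and classification in one call.
#'
#' @param dataset an `insertion_dataset`.
#' @param reference_essential gene ids of the reference essential set used to
#'   anchor the thresholds.
#' @param coverage_excluded gene ids excluded for low coverage.
#' @param total normalization total passed to [compute_insertion_index()].
#' @return list with `records` (classified data.frame) and `thresholds`.
#' @export
tradis_call <- function(dataset, reference_essential,
                        coverage_excluded = character(0),
                        total = c("raw", "curated")) {
  records <- compute_insertion_index(dataset, curated = TRUE, total = total)
  ref <- records$index[records$gene_id %in% reference_essential]
  thresholds <- derive_thresholds(ref)
  list(records = classify_genes(records, thresholds, coverage_excluded),
       thresholds = thresholds)
}

#' Summary arithmetic for an insertion library
#'
#' Average insertions per gene and average gene length for a transposon
#' library, as reported when comparing library coverage between studies.
#'
#' @param coding_bp total size of coding regions (bp).
#' @param n_genes number of genes analysed.
#' @param unique_insertions number of unique insertion sites.
#' @return list with `avg_insertions_per_gene` and `avg_gene_length_bp`.
#' @export
insertion_library_summary <- function(coding_bp, n_genes, unique_insertions) {
  list(avg_insertions_per_gene = unique_insertions / n_genes,
       avg_gene_length_bp = coding_bp / n_genes)
}
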