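# Single-cell NSC state calls: QC, tdTomato recombination, G0/G1 index
# scoring, and dormant/resting/proliferating assignment.

#' The nine G1/S index genes
#'
#' Genes highly and stably expressed across G1 and S phase, used to
#' separate G1 cells from quiescent (G0) cells.
#' @export
INDEX_GENES <- c("Mcm2", "Mcm3", "Mcm4", "Mcm5", "Mcm6", "Mcm7",
                 "Ccne1", "Ccne2", "Pcna")

check_chemistry <- function(chemistry) {
  if (!all(chemistry %in% c("v2", "v3")))
    stop("chemistry must be 'v2' or 'v3'")
  chemistry
}

#' Quality-control gate
#'
#' A cell passes iff it has more than 500 genes detected and fewer than
#' 10% mitochondrial reads (both inequalities strict).
#'
#' @param genes_detected integer vector.
#' @param mito_fraction numeric vector in `[0, 1]`.
#' @return character vector: `"pass"`, `"fail_genes"`, or `"fail_mito"`.
#' @export
qc_filter <- function(genes_detected, mito_fraction) {
  if (any(mito_fraction < 0 | mito_fraction > 1))
    stop("mito_fraction must be in [0, 1]")
  ifelse(genes_detected <= 500, "fail_genes",
         ifelse(mito_fraction >= 0.10, "fail_mito", "pass"))
}

#' Classify reporter recombination (tdTomato)
#'
#' A cell is tdTomato+ if it has fewer than 4 reads of the intact
#' reporter locus and more than 1 read of the recombined locus (v2
#' chemistry). Version 3 chemistry detects about twice as many
#' transcripts, so both thresholds are doubled by default; set
#' `double_intact = FALSE` to double only the positive-evidence
#' (recombined-read) threshold.
#'
#' @param intact_reads reads mapping to the intact reporter locus.
#' @param recombined_reads summed reads of the two recombination-specific
#'   elements (WPRE + bGHpolyA).
#' @param chemistry "v2" or "v3" (recycled).
#' @param double_intact whether v3 doubling also applies to the
#'   intact-locus upper bound.
#' @return logical vector, `TRUE` = tdTomato+.
#' @export
classify_tdtomato <- function(intact_reads, recombined_reads, chemistry,
                              double_intact = TRUE) {
  check_chemistry(chemistry)
  v3 <- chemistry == "v3"
  intact_thr <- ifelse(v3 & double_intact, 8, 4)
  recomb_thr <- ifelse(v3, 2, 1)
  intact_reads < intact_thr & recombined_reads > recomb_thr
}

#' Cell-cycle index score (0-9)
#'
#' The number of the nine index genes detected (>= 1 read) in a cell.
#'
#' @param counts matrix or data frame with the nine index-gene columns
#'   (cells in rows), or a named numeric vector for a single cell.
#' @return integer vector of scores in 0..9.
#' @export
cycle_index_score <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts)))
    counts <- as.data.frame(as.list(counts))
  miss <- setdiff(INDEX_GENES, colnames(counts))
  if (length(miss)) stop("missing index gene column: ", paste(miss, collapse = ", "))
  m <- as.matrix(counts[, INDEX_GENES, drop = FALSE])
  if (any(m < 0)) stop("counts must be >= 0")
  as.integer(rowSums(m >= 1))
}

#' G1 versus quiescent call from the index score
#'
#' Cells with more than 1 index gene detected are in G1; all others are
#' quiescent/post-mitotic. The threshold is doubled for v3 chemistry.
#'
#' @param score integer index scores (0..9).
#' @param chemistry "v2" or "v3" (recycled).
#' @return character vector: `"G1"` or `"quiescent"`.
#' @export
classify_phase <- function(score, chemistry) {
  if (any(score < 0 | score > 9)) stop("score must be in 0..9")
  check_chemistry(chemistry)
  thr <- ifelse(chemistry == "v3", 2, 1)
  ifelse(score > thr, "G1", "quiescent")
}

#' Assign dormant/resting/proliferating state labels
#'
#' Applies the QC gate, tdTomato call, index scoring, and phase call to
#' a table of per-cell records, then assigns: proliferating = G2/S/M
#' flag set (any tdTomato status) or in G1; resting = tdTomato+ and
#' quiescent; dormant = tdTomato- and quiescent; excluded = QC failure.
#' In `strict` mode, phase-based (G1) proliferation calls are restricted
#' to tdTomato+ cells, as when the G1/G0 boundary has only been
#' validated within the recombined population; tdTomato- G1 cells are
#' then labeled dormant.
#'
#' @param cells data frame with the nine index-gene columns plus
#'   `intact_reads, recombined_reads, genes_detected, mito_fraction,
#'   chemistry`, and optionally `g2sm_flag`.
#' @param strict restrict G1-based proliferation calls to tdTomato+ cells.
#' @param double_intact passed to [classify_tdtomato()].
#' @return data frame with `state` (excluded/dormant/resting/
#'   proliferating), `qc`, `tdtomato`, `index_score`, `phase`.
#' @export
assign_state <- function(cells, strict = FALSE, double_intact = TRUE) {
  need <- c(INDEX_GENES, "intact_reads", "recombined_reads", "genes_detected",
            "mito_fraction", "chemistry")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  qc <- qc_filter(cells$genes_detected, cells$mito_fraction)
  td <- classify_tdtomato(cells$intact_reads, cells$recombined_reads,
                          cells$chemistry, double_intact = double_intact)
  score <- cycle_index_score(cells)
  phase <- classify_phase(score, cells$chemistry)
  if (is.null(cells$g2sm_flag)) {
    warning("no g2sm_flag column; classifying from index score and tdTomato alone")
    g2sm <- rep(FALSE, nrow(cells))
  } else g2sm <- isTRUE_vec(cells$g2sm_flag)
  g1_prolif <- phase == "G1" & (td | !strict)
  state <- ifelse(qc != "pass", "excluded",
           ifelse(g2sm | g1_prolif, "proliferating",
           ifelse(td, "resting", "dormant")))
  data.frame(state = state, qc = qc, tdtomato = ifelse(td, "pos", "neg"),
             index_score = score, phase = phase, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a cell matrix (MTX triplet) into per-cell records
#'
#' Reads a MatrixMarket sparse count matrix with its features and
#' barcodes files and derives the per-cell fields the classifier needs:
#' index-gene counts, intact (`tdTomatoLoxP`) and recombined (`WPRE` +
#' `bGHpolyA`) reporter reads, genes detected, and the mitochondrial
#' read fraction (features prefixed `mt-`).
#'
#' @param mtx_path path to the `.mtx` file (features in rows, cells in
#'   columns).
#' @param features_path,barcodes_path paths to the TSV name files.
#' @param chemistry "v2" or "v3" applied to all cells.
#' @return data frame of per-cell records suitable for [assign_state()].
#' @export
read_cell_matrix <- function(mtx_path, features_path, barcodes_path,
                             chemistry = "v2") {
  check_chemistry(chemistry)
  m <- Matrix::readMM(mtx_path)
  features <- read.delim(features_path, header = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("matrix dimensions do not match features/barcodes files")
  rownames(m) <- features
  reporter <- c("tdTomatoLoxP", "WPRE", "bGHpolyA", "eGFP", "tdTomatoCDS")
  miss <- setdiff(c(INDEX_GENES, "tdTomatoLoxP", "WPRE", "bGHpolyA"), features)
  if (length(miss)) stop("matrix lacks required feature: ", paste(miss, collapse = ", "))
  gene_rows <- !(features %in% reporter)
  mg <- m[gene_rows, , drop = FALSE]
  mito <- grepl("^mt-", features[gene_rows])
  tot <- Matrix::colSums(mg)
  rec <- data.frame(barcode = barcodes,
                    genes_detected = Matrix::colSums(mg > 0),
                    mito_fraction = ifelse(tot > 0, Matrix::colSums(mg[mito, , drop = FALSE]) / tot, 0),
                    intact_reads = as.numeric(m["tdTomatoLoxP", ]),
                    recombined_reads = as.numeric(m["WPRE", ] + m["bGHpolyA", ]),
                    chemistry = chemistry, stringsAsFactors = FALSE)
  for (g in INDEX_GENES) rec[[g]] <- as.numeric(m[g, ])
  rec
}
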