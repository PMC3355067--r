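# Conversion of per-gene evidence (antibody staining categories and/or
# expression signals) into per-reaction weights for one tissue.

HPA_LEVELS <- c("high", "medium", "low", "absent")

#' Evidence table constructor
#'
#' One row per (gene, tissue). `hpa_level` is one of `"high"`,
#' `"medium"`, `"low"`, `"absent"` or `NA`; `expression_signal` is a
#' nonnegative number or `NA`. Every row must carry at least one of the
#' two.
#'
#' @param x data.frame with columns `gene`, `tissue`, `hpa_level`,
#'   `expression_signal` (missing columns are added as all-`NA`).
#' @return the validated data.frame with class `evidence_table`.
#' @export
evidence_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "tissue") %in% names(x)))
  if (is.null(x$hpa_level)) x$hpa_level <- NA_character_
  if (is.null(x$expression_signal)) x$expression_signal <- NA_real_
  bad <- !is.na(x$hpa_level) & !(x$hpa_level %in% HPA_LEVELS)
  if (any(bad)) {
    stop("unknown HPA level(s): ", paste(unique(x$hpa_level[bad]),
                                         collapse = ", "))
  }
  if (any(!is.na(x$expression_signal) & x$expression_signal < 0)) {
    stop("expression signals must be nonnegative")
  }
  if (any(is.na(x$hpa_level) & is.na(x$expression_signal))) {
    stop("every row needs an HPA level or an expression signal")
  }
  class(x) <- c("evidence_table", "data.frame")
  x
}

#' Read an evidence table from TSV
#'
#' Expects columns `gene`, `tissue`, `hpa_level`, `expression_signal`
#' (empty strings read as `NA`).
#'
#' @param path TSV file.
#' @return an `evidence_table`.
#' @export
read_evidence <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         na.strings = c("NA", ""))
  evidence_table(x)
}

#' Weighting configuration
#'
#' Defaults follow the published scheme: staining categories high /
#' medium / low / absent score 20 / 15 / 10 / -8; reactions with no
#' scored gene get -2. Expression weights are
#' `expression_scale * log_base((signal + pc) / (mean + pc))`; the scale
#' default (10, base 2) makes a 2-fold change score like a "low"
#' staining call.
#'
#' @param hpa_weights named numeric over the four staining levels.
#' @param no_evidence_weight weight for reactions with no usable gene
#'   evidence (must be negative).
#' @param expression_scale positive multiplier on the log-ratio.
#' @param expression_log_base logarithm base.
#' @param expression_pseudocount nonnegative; `NULL` picks half the
#'   smallest positive signal (or 1 when all signals are integers) at
#'   scoring time.
#' @return a list with class `weight_config`.
#' @export
weight_config <- function(hpa_weights = c(high = 20, medium = 15,
                                          low = 10, absent = -8),
                          no_evidence_weight = -2,
                          expression_scale = 10,
                          expression_log_base = 2,
                          expression_pseudocount = NULL) {
  stopifnot(all(HPA_LEVELS %in% names(hpa_weights)))
  hw <- hpa_weights[HPA_LEVELS]
  if (!(hw["high"] >= hw["medium"] && hw["medium"] >= hw["low"] &&
        hw["low"] > 0 && hw["absent"] < 0)) {
    stop("need high >= medium >= low > 0 > absent")
  }
  if (no_evidence_weight >= 0) stop("no_evidence_weight must be negative")
  stopifnot(expression_scale > 0, expression_log_base > 1)
  structure(list(hpa_weights = hw,
                 no_evidence_weight = no_evidence_weight,
                 expression_scale = expression_scale,
                 expression_log_base = expression_log_base,
                 expression_pseudocount = expression_pseudocount),
            class = "weight_config")
}

#' Weight of a staining category
#'
#' @param level one of `"high"`, `"medium"`, `"low"`, `"absent"`
#'   (vectorised).
#' @param config a [weight_config()].
#' @return numeric weight(s).
#' @export
hpa_gene_weight <- function(level, config = weight_config()) {
  bad <- !(level %in% HPA_LEVELS)
  if (any(bad)) stop("unknown HPA level(s): ",
                     paste(unique(level[bad]), collapse = ", "))
  unname(config$hpa_weights[level])
}

default_pseudocount <- function(signals) {
  pos <- signals[!is.na(signals) & signals > 0]
  if (!length(pos)) return(1)
  if (all(abs(signals - round(signals)) < 1e-12, na.rm = TRUE)) return(1)
  min(pos) / 2
}

#' Expression-based gene weight
#'
#' The signal in the target tissue is compared to the arithmetic mean of
#' the gene's signal over all tissues: positive weight above the mean,
#' negative below, zero at the mean; strictly increasing in the signal.
#'
#' @param signal the gene's signal in the target tissue.
#' @param all_tissue_signals the gene's signals across all tissues
#'   (including the target).
#' @param config a [weight_config()].
#' @return numeric weight.
#' @export
expression_gene_weight <- function(signal, all_tissue_signals,
                                   config = weight_config()) {
  stopifnot(length(all_tissue_signals) >= 1)
  pc <- config$expression_pseudocount
  if (is.null(pc)) pc <- default_pseudocount(all_tissue_signals)
  mu <- mean(all_tissue_signals)
  if (mu + pc <= 0 || signal + pc <= 0) {
    stop("undefined expression ratio: all-zero signals with zero ",
         "pseudocount")
  }
  config$expression_scale *
    log((signal + pc) / (mu + pc), base = config$expression_log_base)
}

#' Per-gene evidence scores for one tissue
#'
#' Staining evidence takes precedence over expression for the same gene;
#' genes with neither get `NA`.
#'
#' @param evidence an [evidence_table()].
#' @param tissue tissue id.
#' @param config a [weight_config()].
#' @return data.frame with columns `gene`, `score`, `source`
#'   (`"hpa"`/`"expression"`/`"none"`), `hpa_level`.
#' @export
gene_scores <- function(evidence, tissue, config = weight_config()) {
  genes <- unique(evidence$gene)
  score <- rep(NA_real_, length(genes))
  source <- rep("none", length(genes))
  level <- rep(NA_character_, length(genes))
  for (k in seq_along(genes)) {
    rows <- evidence[evidence$gene == genes[k], , drop = FALSE]
    here <- rows[rows$tissue == tissue, , drop = FALSE]
    if (nrow(here) && !is.na(here$hpa_level[1])) {
      score[k] <- hpa_gene_weight(here$hpa_level[1], config)
      source[k] <- "hpa"
      level[k] <- here$hpa_level[1]
    } else if (nrow(here) && !is.na(here$expression_signal[1])) {
      sig <- rows$expression_signal[!is.na(rows$expression_signal)]
      score[k] <- expression_gene_weight(here$expression_signal[1], sig,
                                         config)
      source[k] <- "expression"
    }
  }
  data.frame(gene = genes, score = score, source = source,
             hpa_level = level, stringsAsFactors = FALSE)
}

#' Per-reaction evidence weights for one tissue
#'
#' Each non-exchange reaction scores the maximum over the genes in its
#' GPR (the AND/OR structure is deliberately ignored). Reactions with no
#' gene, or none of whose genes have evidence, get the no-evidence
#' default; exchange reactions get 0.
#'
#' @param model a `metabolic_model`.
#' @param evidence an [evidence_table()] (may have zero rows).
#' @param tissue tissue id.
#' @param config a [weight_config()].
#' @return a data.frame with class `weight_vector`: columns `reaction`,
#'   `weight`, `source_gene`, `source_type`, `source_level`.
#' @export
reaction_weights <- function(model, evidence, tissue,
                             config = weight_config()) {
  gs <- if (nrow(evidence)) gene_scores(evidence, tissue, config)
        else data.frame(gene = character(0), score = numeric(0),
                        source = character(0), hpa_level = character(0))
  score_of <- stats::setNames(gs$score, gs$gene)
  rxns <- model$reactions$id
  w <- numeric(length(rxns))
  src_gene <- rep(NA_character_, length(rxns))
  src_type <- rep("none", length(rxns))
  src_level <- rep(NA_character_, length(rxns))
  for (k in seq_along(rxns)) {
    if (model$reactions$is_exchange[k]) {
      w[k] <- 0
      src_type[k] <- "exchange"
      next
    }
    genes <- gpr_genes(model$gprs[[rxns[k]]])
    sc <- score_of[genes]
    sc <- sc[!is.na(sc)]
    if (!length(sc)) {
      w[k] <- config$no_evidence_weight
      next
    }
    best <- names(sc)[which.max(sc)]
    w[k] <- max(sc)
    src_gene[k] <- best
    src_type[k] <- gs$source[gs$gene == best]
    src_level[k] <- gs$hpa_level[gs$gene == best]
  }
  structure(data.frame(reaction = rxns, weight = w, source_gene = src_gene,
                       source_type = src_type, source_level = src_level,
                       stringsAsFactors = FALSE),
            class = c("weight_vector", "data.frame"))
}

#' Extract a named weight vector
#'
#' @param wv a `weight_vector`.
#' @return named numeric: reaction id -> weight.
#' @export
weights_as_vector <- function(wv) {
  stats::setNames(wv$weight, wv$reaction)
}
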