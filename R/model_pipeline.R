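# Training-set construction with the REVEL prior-weighting scheme, and the
# weighted logistic-regression and random-forest pathogenicity models.

LRM_FEATURES <- c("overlap", "tumor_count_change", "tumor_count_residue",
                  "phylop_mam20", "phylop_vert7", "phastcons_mam20",
                  "phastcons_vert7")
CONSERVATION_FEATURES <- c("phylop_mam20", "phylop_vert7",
                           "phastcons_mam20", "phastcons_vert7")

#' Build the supervised-learning training set
#'
#' Converts annotated germline records into weighted training examples:
#'
#' 1. keep records with germline allele origin;
#' 2. group different nucleotide variants producing the same amino-acid
#'    change, keyed on (gene, residue, ref_aa, alt_aa) — on label
#'    disagreement the precedence LP/P > LB/B > VUS wins, and the maximum
#'    REVEL and tumor counts within the group are kept;
#' 3. drop records whose label is outside \{LP/P, VUS, LB/B\};
#' 4. drop VUS with REVEL above the cutoff (strictly) or missing REVEL —
#'    the retained low-REVEL VUS are relabelled benign to counter the class
#'    imbalance, with prior weight `1 - REVEL` reflecting residual doubt;
#'    true LB/B and all LP/P examples get weight 1;
#' 5. restrict to the gene whitelist (by default the genes carrying at
#'    least one hotspot-overlapping grouped variant).
#'
#' @param germline Annotated germline records ([annotate_overlap()]).
#' @param revel_cutoff Strict upper REVEL bound for retained VUS
#'   (default 0.29, the upper bound of the BP4-supporting band).
#' @param gene_whitelist Character vector of genes to keep; `NULL` derives
#'   it from the overlap annotation. `character(0)` is an error.
#' @param tie_rule Label precedence for grouped variants.
#' @return A list with `examples` (data.frame of features, `label` in
#'   \{0,1\}, `weight`) and `report`, a named integer vector of telescoping
#'   counts: each step's output is the next step's input.
#' @export
build_training_set <- function(germline, revel_cutoff = 0.29,
                               gene_whitelist = NULL,
                               tie_rule = c("LP_P", "LB_B", "VUS")) {
  if (!is.null(gene_whitelist) && length(gene_whitelist) == 0) {
    stop("gene whitelist is empty")
  }
  if (any(is.na(germline$overlaps_hotspot))) {
    stop("records are not overlap-annotated; run annotate_overlap() first")
  }
  n_input <- nrow(germline)
  g <- germline[germline$allele_origin == "germline", , drop = FALSE]
  n_germline <- nrow(g)

  grouped <- group_by_aa_change(g, tie_rule)
  n_grouped <- nrow(grouped)

  grouped <- grouped[grouped$label %in% c("LP_P", "VUS", "LB_B"), , drop = FALSE]
  n_classifiable <- nrow(grouped)

  is_vus <- grouped$label == "VUS"
  drop_vus <- is_vus & (is.na(grouped$revel) | grouped$revel > revel_cutoff)
  grouped <- grouped[!drop_vus, , drop = FALSE]
  n_after_revel <- nrow(grouped)

  if (is.null(gene_whitelist)) {
    gene_whitelist <- sort(unique(grouped$gene[grouped$overlaps_hotspot]))
    if (length(gene_whitelist) == 0) {
      stop("no overlapping variants from which to derive a gene whitelist")
    }
  }
  grouped <- grouped[grouped$gene %in% gene_whitelist, , drop = FALSE]
  n_final <- nrow(grouped)

  examples <- data.frame(
    gene = grouped$gene, residue = grouped$residue,
    ref_aa = grouped$ref_aa, alt_aa = grouped$alt_aa,
    overlap = as.integer(grouped$overlaps_hotspot),
    tumor_count_change = grouped$tumor_count_change,
    tumor_count_residue = grouped$tumor_count_residue,
    phylop_mam20 = grouped$phylop_mam20,
    phylop_vert7 = grouped$phylop_vert7,
    phastcons_mam20 = grouped$phastcons_mam20,
    phastcons_vert7 = grouped$phastcons_vert7,
    label = as.integer(grouped$label == "LP_P"),
    weight = ifelse(grouped$label == "VUS", 1 - grouped$revel, 1),
    stringsAsFactors = FALSE
  )
  report <- c(n_input = n_input, n_germline_origin = n_germline,
              n_grouped = n_grouped, n_classifiable = n_classifiable,
              n_after_revel_filter = n_after_revel, n_final = n_final,
              n_overlap = sum(examples$overlap),
              n_genes = length(unique(examples$gene)))
  list(examples = examples, report = report,
       gene_whitelist = gene_whitelist)
}

group_by_aa_change <- function(g, tie_rule = c("LP_P", "LB_B", "VUS")) {
  if (nrow(g) == 0) return(g)
  key <- paste(g$gene, g$residue, g$ref_aa, g$alt_aa, sep = "|")
  prec <- match(g$label, c(tie_rule, setdiff(CLASS_LABELS, tie_rule)))
  ord <- order(key, prec)
  g <- g[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- g[first, , drop = FALSE]
  grp <- match(key, key[first])
  max_na <- function(x, grp) {
    v <- tapply(x, grp, function(y) if (all(is.na(y))) NA_real_ else max(y, na.rm = TRUE))
    as.numeric(v)
  }
  out$revel <- max_na(g$revel, grp)
  out$tumor_count_change <- as.integer(max_na(g$tumor_count_change, grp))
  out$tumor_count_residue <- as.integer(max_na(g$tumor_count_residue, grp))
  out$overlaps_hotspot <- as.logical(tapply(g$overlaps_hotspot, grp, any))
  out
}

muffle_weight_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer #successes", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

weighted_loglik <- function(y, p, w) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Fit the weighted logistic-regression pathogenicity model
#'
#' Weighted maximum-likelihood logistic regression of the LP/P label on the
#' overlap flag, gene (treatment-coded categorical, reference level =
#' alphabetically first gene), the two tumor-sample counts and the four
#' conservation scores. Relabelled VUS enter with their prior weight
#' `1 - REVEL`.
#'
#' @param training Output of [build_training_set()] or its `examples`.
#' @param use_gene Include the gene factor (drop for single-gene fits or to
#'   mirror the gene-free forest).
#' @param use_conservation Include the four conservation scores (drop for
#'   the conservation-ablation fit).
#' @return A `duality_lrm`: the glm fit, per-example `scores`,
#'   `mcfadden_r2` (1 - l_model/l_null against the weighted intercept-only
#'   model), `aic`, and the trained `gene_levels`.
#' @export
fit_lrm <- function(training, use_gene = TRUE, use_conservation = TRUE) {
  ex <- if (is.data.frame(training)) training else training$examples
  if (length(unique(ex$label)) < 2) stop("training data contain a single class")
  feats <- LRM_FEATURES
  if (!use_conservation) feats <- setdiff(feats, CONSERVATION_FEATURES)
  gene_levels <- sort(unique(ex$gene))
  use_gene <- use_gene && length(gene_levels) > 1
  df <- ex[, c(feats, "label", "weight"), drop = FALSE]
  if (use_gene) df$gene <- factor(ex$gene, levels = gene_levels)
  rhs <- paste(c(if (use_gene) "gene", feats), collapse = " + ")
  fml <- stats::as.formula(paste("label ~", rhs))
  fit <- muffle_weight_warning(
    stats::glm(fml, family = stats::binomial(), data = df, weights = df$weight)
  )
  if (!fit$converged) {
    eps <- 1e-8
    separated <- any(stats::fitted(fit) > 1 - eps | stats::fitted(fit) < eps)
    if (separated) {
      warning("complete separation detected; coefficients reported at the ",
              "iteration cap (", fit$iter, " iterations)")
    } else {
      stop("logistic regression did not converge after ", fit$iter,
           " iterations")
    }
  }
  p <- as.numeric(stats::fitted(fit))
  ll <- weighted_loglik(df$label, p, df$weight)
  null_fit <- muffle_weight_warning(
    stats::glm(label ~ 1, family = stats::binomial(), data = df,
               weights = df$weight)
  )
  ll0 <- weighted_loglik(df$label, as.numeric(stats::fitted(null_fit)), df$weight)
  r2 <- if (ll0 == 0) 0 else 1 - ll / ll0
  structure(
    list(kind = "LRM", fit = fit, scores = p, mcfadden_r2 = r2,
         aic = stats::AIC(fit), gene_levels = if (use_gene) gene_levels else NULL,
         features = feats, use_gene = use_gene),
    class = "duality_lrm"
  )
}

#' Fit the random-forest pathogenicity model
#'
#' Classification forest on the same predictors as the logistic model minus
#' the gene factor (excluded for its high cardinality). Per-example
#' probability is the fraction of trees voting pathogenic; the out-of-bag
#' error uses only out-of-bag votes. Example weights are ignored: the
#' reference forest implementation takes no case weights.
#'
#' @param training Output of [build_training_set()] or its `examples`.
#' @param n_trees Number of trees (default 350).
#' @param vars_per_split Predictors tried at each split (default 4).
#' @param seed Integer seed; the same seed reproduces scores exactly.
#' @param use_conservation Include the four conservation scores.
#' @return A `duality_rfm`: the forest, per-example OOB-vote `scores`,
#'   `oob_error`, `seed`.
#' @export
fit_rfm <- function(training, n_trees = 350, vars_per_split = 4, seed = 1,
                    use_conservation = TRUE) {
  ex <- if (is.data.frame(training)) training else training$examples
  if (length(unique(ex$label)) < 2) stop("training data contain a single class")
  feats <- setdiff(LRM_FEATURES,
                   if (use_conservation) character() else CONSERVATION_FEATURES)
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (vars_per_split > length(feats)) {
    stop("vars_per_split exceeds the number of predictors (", length(feats), ")")
  }
  x <- ex[, feats, drop = FALSE]
  y <- factor(ex$label, levels = c(0, 1))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = vars_per_split)
  structure(
    list(kind = "RFM", fit = fit,
         scores = as.numeric(predict(fit, x, type = "prob")[, "1"]),
         oob_scores = as.numeric(fit$votes[, "1"]),
         oob_error = as.numeric(fit$err.rate[n_trees, "OOB"]),
         seed = seed, features = feats,
         hyperparams = list(n_trees = n_trees, vars_per_split = vars_per_split)),
    class = "duality_rfm"
  )
}

check_features <- function(newdata, feats) {
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
}

#' Predict pathogenicity probabilities from the logistic model
#'
#' @param object A `duality_lrm`.
#' @param newdata Data.frame with the model's feature columns (and `gene`
#'   when the model includes the gene factor — genes outside the trained
#'   levels are an error, mirroring the model's gene restriction).
#' @param ... Unused.
#' @return Numeric probabilities in \[0,1\].
#' @export
predict.duality_lrm <- function(object, newdata, ...) {
  check_features(newdata, object$features)
  df <- newdata
  if (object$use_gene) {
    check_features(newdata, "gene")
    unseen <- setdiff(unique(newdata$gene), object$gene_levels)
    if (length(unseen) > 0) {
      stop("gene(s) outside the trained levels: ",
           paste(unseen, collapse = ", "))
    }
    df$gene <- factor(df$gene, levels = object$gene_levels)
  }
  as.numeric(stats::predict(object$fit, newdata = df, type = "response"))
}

#' Predict pathogenicity probabilities from the random forest
#'
#' @param object A `duality_rfm`.
#' @param newdata Data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Vote-fraction probabilities in \[0,1\].
#' @export
predict.duality_rfm <- function(object, newdata, ...) {
  check_features(newdata, object$features)
  as.numeric(predict(object$fit, newdata[, object$features, drop = FALSE],
                     type = "prob")[, "1"])
}

#' @export
print.duality_lrm <- function(x, ...) {
  cat(sprintf("weighted logistic pathogenicity model: %d examples, %s%d predictors\nMcFadden pseudo-R2 = %.3f, AIC = %.1f\n",
              length(x$scores),
              if (x$use_gene) sprintf("%d gene levels + ", length(x$gene_levels)) else "",
              length(x$features), x$mcfadden_r2, x$aic))
  invisible(x)
}

#' @export
print.duality_rfm <- function(x, ...) {
  cat(sprintf("random-forest pathogenicity model: %d trees, %d vars/split, OOB error = %.3f (seed %d)\n",
              x$hyperparams$n_trees, x$hyperparams$vars_per_split,
              x$oob_error, x$seed))
  invisible(x)
}
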