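.featureColumns <- c("pearson", "jaccard", "apex", "mi", "bayes")

# Feature matrix in fixed column order; NA (feature undefined in every
# shared experiment) becomes 0, i.e. "no evidence".
.featureMatrix <- function(featureTable, featureNames = .featureColumns) {
    X <- as.matrix(featureTable[, featureNames, drop = FALSE])
    X[is.na(X)] <- 0
    X
}

#' Train the co-complex classifier
#'
#' Fits a bagged ensemble of randomised decision trees (random forest) that
#' maps a pair's five aggregated co-elution features to the probability
#' that the two proteins belong to a common complex. Training pairs come
#' from a gold-standard complex set via \code{\link{deriveLabels}};
#' unlabelled pairs are scored later but never used in training.
#'
#' @param featureTable feature table from \code{\link{buildFeatureTable}}.
#' @param labels output of \code{\link{deriveLabels}} (only
#'   \code{positives} and \code{negatives} are used).
#' @param ntree number of trees.
#' @param seed RNG seed; the fit is deterministic under it.
#' @return A \linkS4class{TrainedPPIModel}.
#' @export
trainPPIClassifier <- function(featureTable, labels, ntree = 500L,
                               seed = 1L) {
    key <- .pairKey(featureTable$idA, featureTable$idB)
    posKey <- .pairKey(labels$positives$idA, labels$positives$idB)
    negKey <- .pairKey(labels$negatives$idA, labels$negatives$idB)
    y <- rep(NA_character_, nrow(featureTable))
    y[key %in% posKey] <- "positive"
    y[key %in% negKey] <- "negative"
    keep <- !is.na(y)
    nPos <- sum(y[keep] == "positive")
    nNeg <- sum(y[keep] == "negative")
    if (nPos < 10L || nNeg < 10L)
        .stopf("need >= 10 positives and >= 10 negatives with features (got %d / %d)",
               nPos, nNeg)
    X <- .featureMatrix(featureTable[keep, , drop = FALSE])
    yf <- factor(y[keep], levels = c("negative", "positive"))
    fit <- withr::with_seed(seed,
        randomForest::randomForest(x = X, y = yf, ntree = ntree))
    new("TrainedPPIModel", fit = fit, featureNames = .featureColumns,
        nPositive = as.integer(nPos), nNegative = as.integer(nNeg),
        seed = as.integer(seed))
}

#' Predict co-complex probabilities for a feature table
#'
#' @param object a \linkS4class{TrainedPPIModel}.
#' @param featureTable feature table with the model's feature columns.
#' @param ... ignored.
#' @return Numeric vector of probabilities in [0, 1], one per row.
#' @export
setMethod("predict", "TrainedPPIModel", function(object, featureTable, ...) {
    if (!all(object@featureNames %in% colnames(featureTable)))
        .stopf("feature table lacks the model's feature columns (%s)",
               paste(object@featureNames, collapse = ", "))
    X <- .featureMatrix(featureTable, object@featureNames)
    unname(stats::predict(object@fit, X, type = "prob")[, "positive"])
})

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the observed scores, computing the
#' true- and false-positive rates at each, and integrates the curve with
#' the trapezoid rule. Equivalent to the Mann-Whitney U statistic
#' normalised by the number of positive-negative comparisons (ties count
#' one half).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical or 0/1 vector of true labels.
#' @return list with \code{roc} (data.frame \code{threshold}, \code{fpr},
#'   \code{tpr}), \code{auc}, and \code{pr} (data.frame \code{recall},
#'   \code{precision}).
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.logical(labels)
    if (!any(labels) || all(labels))
        .stopf("ROC needs both classes")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    nPos <- sum(l); nNeg <- sum(!l)
    tp <- cumsum(l); fp <- cumsum(!l)
    last <- !duplicated(s, fromLast = TRUE)   # one point per threshold
    thr <- s[last]
    tpr <- c(0, tp[last] / nPos)
    fpr <- c(0, fp[last] / nNeg)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    prec <- tp[last] / (tp[last] + fp[last])
    list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
         auc = auc,
         pr = data.frame(recall = tp[last] / nPos, precision = prec))
}

#' Complex-level cross-validated evaluation of the classifier
#'
#' Trains on all labelled pairs outside each fold of a complex-level split
#' and predicts the held-out fold; pooled out-of-fold predictions give the
#' ROC curve and AUC. Folds containing a single class are skipped with a
#' warning.
#'
#' @param featureTable feature table from \code{\link{buildFeatureTable}}.
#' @param pairFolds output of \code{\link{assignPairFolds}}; rows with
#'   \code{NA} fold are ignored.
#' @param ntree trees per fold model.
#' @param seed RNG seed (per-fold seeds derive from it).
#' @return list with \code{predictions} (data.frame \code{idA}, \code{idB},
#'   \code{label}, \code{fold}, \code{score}), \code{roc}, \code{auc},
#'   \code{pr}.
#' @export
crossValidatePPIClassifier <- function(featureTable, pairFolds,
                                       ntree = 500L, seed = 1L) {
    pf <- pairFolds[!is.na(pairFolds$fold), , drop = FALSE]
    key <- .pairKey(featureTable$idA, featureTable$idB)
    pf <- pf[.pairKey(pf$idA, pf$idB) %in% key, , drop = FALSE]
    preds <- NULL
    for (f in sort(unique(pf$fold))) {
        test <- pf[pf$fold == f, , drop = FALSE]
        train <- pf[pf$fold != f, , drop = FALSE]
        if (length(unique(test$label)) < 2L) {
            .warnf("fold %d holds a single class; skipped", f)
            next
        }
        trLabels <- list(
            positives = train[train$label == "positive", c("idA", "idB")],
            negatives = train[train$label == "negative", c("idA", "idB")])
        model <- trainPPIClassifier(featureTable, trLabels, ntree = ntree,
                                    seed = seed + f)
        teIdx <- match(.pairKey(test$idA, test$idB), key)
        sc <- predict(model, featureTable[teIdx, , drop = FALSE])
        preds <- rbind(preds, data.frame(test, score = sc,
                                         stringsAsFactors = FALSE))
    }
    if (is.null(preds)) .stopf("no evaluable fold")
    ev <- rocCurve(preds$score, preds$label == "positive")
    list(predictions = preds, roc = ev$roc, auc = ev$auc, pr = ev$pr)
}

#' Score all candidate pairs and threshold into a network
#'
#' Applies the trained classifier to every candidate pair and retains
#' pairs with probability >= \code{threshold} as the weighted interaction
#' network (edge weight = probability; zero-probability pairs are never
#' edges).
#'
#' @param model a \linkS4class{TrainedPPIModel}.
#' @param featureTable feature table covering all candidate pairs.
#' @param threshold retention probability in [0, 1].
#' @return A \linkS4class{WeightedPPINetwork}.
#' @export
scoreNetwork <- function(model, featureTable, threshold = 0.5) {
    p <- predict(model, featureTable)
    keep <- p >= threshold & p > 0
    edges <- data.frame(idA = featureTable$idA[keep],
                        idB = featureTable$idB[keep],
                        weight = p[keep], stringsAsFactors = FALSE)
    weightedPPINetwork(edges)
}
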