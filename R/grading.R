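## Low- vs high-grade classification: class-weighted soft-margin RBF SVM
## (libsvm via e1071), wrapped by a genetic algorithm that selects the
## feature subset and the (C, gamma) pair. The GA fitness is
## 0.8 * (sensitivity * specificity) + 0.2 / k, with sensitivity and
## specificity measured by stratified inner cross-validation on the
## training data. Performance is reported as six indices over stratified
## tenfold cross-validation with a pooled confusion matrix.

grade_levels <- c("low", "high")   # "high" is the positive class

as_grade <- function(labels) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% grade_levels))
  factor(labels, levels = grade_levels)
}

#' Reciprocal class-weight ratio for unbalanced grades
#'
#' The soft-margin penalty on high-grade errors relative to low-grade ones
#' is the reciprocal of the class-count ratio: `weight(high)/weight(low) =
#' n_low / n_high`, so the rarer class is penalised proportionally more.
#'
#' @param n_low,n_high class counts (both > 0).
#' @return the ratio `n_low / n_high`.
#' @export
class_weight_ratio <- function(n_low, n_high) {
  stopifnot(n_low > 0, n_high > 0)
  n_low / n_high
}

#' Confusion matrix of grade predictions
#'
#' @param truth,predicted factors/characters of "low"/"high"; "high" is the
#'   positive class.
#' @return object of class `confusion_matrix`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_grade(truth); predicted <- as_grade(predicted)
  structure(list(
    TP = sum(truth == "high" & predicted == "high"),
    FP = sum(truth == "low" & predicted == "high"),
    TN = sum(truth == "low" & predicted == "low"),
    FN = sum(truth == "high" & predicted == "low")),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d  TN %d  FP %d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Performance indices from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`; an index with a zero
#' denominator is `NA`.
#'
#' @param cm a [confusion_matrix()] (or list with TP/FP/TN/FN).
#' @return named numeric vector
#'   `c(accuracy, sensitivity, specificity, PPV, NPV)`, as fractions.
#' @export
metrics_from_confusion <- function(cm) {
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, c(
    accuracy = sdiv(TP + TN, TP + TN + FP + FN),
    sensitivity = sdiv(TP, TP + FN),
    specificity = sdiv(TN, TN + FP),
    PPV = sdiv(TP, TP + FP),
    NPV = sdiv(TN, TN + FN)))
}

#' Area under the ROC curve (A_Z)
#'
#' Mann-Whitney formulation: the probability that a random high-grade case
#' scores above a random low-grade case, ties counted one half.
#'
#' @param scores numeric decision values (larger = more high-grade).
#' @param labels "low"/"high" per score.
#' @return A_Z in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_grade(labels)
  pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' GA fitness of a candidate model
#'
#' `0.8 * sensitivity * specificity + 0.2 / k` where `k` is the number of
#' selected features: strictly increasing in the sensitivity-specificity
#' product, strictly decreasing in the subset size.
#'
#' @param sens,spec fractions in \[0, 1\].
#' @param k number of selected features (>= 1).
#' @param w_perf,w_parsimony the two weights (defaults 0.8 and 0.2).
#' @return fitness value.
#' @export
ga_fitness <- function(sens, spec, k, w_perf = 0.8, w_parsimony = 0.2) {
  stopifnot(k >= 1)
  w_perf * sens * spec + w_parsimony / k
}

## Stratified fold assignment: within each class, shuffled cases are dealt
## round-robin to folds. Uses the current RNG state.
stratified_folds <- function(y, k) {
  y <- as_grade(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Fit the weighted RBF SVM and return decision scores oriented so larger =
## more "high". `x` rows = cases.
svm_fit <- function(x, y, C, gamma, weight_ratio) {
  y <- droplevels(as_grade(y))
  # constant columns are legal (libsvm leaves them unscaled); keep quiet
  withCallingHandlers(
    e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = TRUE,
               class.weights = c(low = 1, high = weight_ratio)[levels(y)]),
    warning = function(w) {
      if (grepl("constant. Cannot scale", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

svm_scores <- function(model, newdata) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  # libsvm orients the decision value toward the first training class
  if (grepl("^low/", colnames(dv)[1])) s <- -s
  list(class = factor(as.character(pr), levels = grade_levels), score = s)
}

## Pooled inner-CV sensitivity/specificity of a candidate (subset, C, gamma).
inner_cv_perf <- function(x, y, C, gamma, weight_ratio, folds) {
  pred <- factor(rep(NA_character_, length(y)), levels = grade_levels)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(c(sens = 0, spec = 0))
    m <- svm_fit(x[tr, , drop = FALSE], y[tr], C, gamma, weight_ratio)
    pred[!tr] <- svm_scores(m, x[!tr, , drop = FALSE])$class
  }
  cm <- confusion_matrix(y, pred)
  met <- metrics_from_confusion(cm)
  sens <- unname(met["sensitivity"]); spec <- unname(met["specificity"])
  c(sens = ifelse(is.na(sens), 0, sens), spec = ifelse(is.na(spec), 0, spec))
}

#' Fit a GA-selected, class-weighted RBF SVM grading model
#'
#' Runs a genetic algorithm over chromosomes made of one selection bit per
#' feature plus real-valued `log2(C)` and `log2(gamma)` genes. Each
#' candidate is scored by [ga_fitness()] with sensitivity and specificity
#' from stratified inner cross-validation on the training data (the outer
#' evaluation never leaks in). The final model is refit on all supplied
#' cases with the best chromosome.
#'
#' @param x numeric matrix or data frame of features (rows = cases). Rows
#'   with missing values are rejected.
#' @param y grade labels, "low"/"high".
#' @param ga a [ga_config()].
#' @param seed integer seed; the whole search is reproducible given it.
#' @param weight_ratio high-vs-low error-penalty ratio; default is the
#'   reciprocal class-count ratio ([class_weight_ratio()]).
#' @return object of class `ga_svm` with elements `features` (selected
#'   names), `C`, `gamma`, `weight_ratio`, `fitness`, `trace` (best fitness
#'   per generation), `model` (the refitted e1071 svm), `levels`, `call`.
#' @seealso [predict.ga_svm()], [tenfold_cv()]
#' @export
ga_svm <- function(x, y, ga = ga_config(), seed = 1L,
                   weight_ratio = NULL) {
  cl <- match.call()
  x <- as.matrix(as.data.frame(x, check.names = FALSE, optional = TRUE))
  y <- as_grade(y)
  if (anyNA(x)) stop("feature matrix contains missing values; ",
                     "drop incomplete cases before fitting", call. = FALSE)
  if (ncol(x) < 2) stop("need at least 2 features", call. = FALSE)
  if (min(table(y)) < 2) stop("need at least 2 cases per class", call. = FALSE)
  if (is.null(weight_ratio)) {
    weight_ratio <- class_weight_ratio(sum(y == "low"), sum(y == "high"))
  }
  p <- ncol(x)
  set.seed(seed)
  folds <- stratified_folds(y, ga$inner_folds)

  rand_chrom <- function() {
    list(bits = stats::runif(p) < 0.5,
         log2C = stats::runif(1, ga$log2C_range[1], ga$log2C_range[2]),
         log2g = stats::runif(1, ga$log2gamma_range[1], ga$log2gamma_range[2]))
  }
  repair <- function(ch) {
    if (!any(ch$bits)) ch$bits[sample.int(p, 1)] <- TRUE
    ch$log2C <- min(max(ch$log2C, ga$log2C_range[1]), ga$log2C_range[2])
    ch$log2g <- min(max(ch$log2g, ga$log2gamma_range[1]), ga$log2gamma_range[2])
    ch
  }
  evaluate <- function(ch) {
    k <- sum(ch$bits)
    perf <- inner_cv_perf(x[, ch$bits, drop = FALSE], y,
                          2^ch$log2C, 2^ch$log2g, weight_ratio, folds)
    ga_fitness(perf[["sens"]], perf[["spec"]], k, ga$w_perf, ga$w_parsimony)
  }
  crossover <- function(a, b) {
    # one-point over the 46-locus chromosome (bits then the two reals)
    cut <- sample.int(p + 1L, 1)   # cut after locus `cut`
    child <- a
    if (cut <= p) {
      if (cut < p) child$bits[(cut + 1L):p] <- b$bits[(cut + 1L):p]
      child$log2C <- b$log2C; child$log2g <- b$log2g
    } else {
      child$log2g <- b$log2g
    }
    child
  }
  mutate <- function(ch) {
    flip <- stats::runif(p) < ga$mutation_rate
    ch$bits[flip] <- !ch$bits[flip]
    if (stats::runif(1) < ga$mutation_rate * 5) {
      ch$log2C <- ch$log2C + stats::rnorm(1, 0, ga$sigma_mut)
    }
    if (stats::runif(1) < ga$mutation_rate * 5) {
      ch$log2g <- ch$log2g + stats::rnorm(1, 0, ga$sigma_mut)
    }
    ch
  }
  tournament <- function(fit) {
    i <- sample.int(length(fit), 2)
    i[which.max(fit[i])]
  }

  pop <- replicate(ga$population, repair(rand_chrom()), simplify = FALSE)
  fit <- vapply(pop, evaluate, numeric(1))
  trace <- numeric(ga$generations)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(ga$elitism)]]
    elite_fit <- fit[ord[seq_len(ga$elitism)]]
    newpop <- vector("list", ga$population)
    newfit <- numeric(ga$population)
    newpop[seq_len(ga$elitism)] <- elite
    newfit[seq_len(ga$elitism)] <- elite_fit
    for (i in (ga$elitism + 1L):ga$population) {
      a <- pop[[tournament(fit)]]
      child <- if (stats::runif(1) < ga$crossover_rate) {
        crossover(a, pop[[tournament(fit)]])
      } else a
      child <- repair(mutate(child))
      newpop[[i]] <- child
      newfit[i] <- evaluate(child)
    }
    pop <- newpop; fit <- newfit
    trace[gen] <- max(fit)
  }
  best <- pop[[which.max(fit)]]
  sel <- colnames(x)[best$bits]
  final <- svm_fit(x[, best$bits, drop = FALSE], y,
                   2^best$log2C, 2^best$log2g, weight_ratio)
  structure(list(
    features = sel, C = 2^best$log2C, gamma = 2^best$log2g,
    weight_ratio = weight_ratio, fitness = max(fit), trace = trace,
    model = final, levels = grade_levels, seed = seed, ga = ga, call = cl),
    class = "ga_svm")
}

#' @export
print.ga_svm <- function(x, ...) {
  cat("GA-selected class-weighted RBF SVM grading model\n")
  cat(sprintf("  %d selected features, C = %.4g, gamma = %.4g, weight ratio = %.3f\n",
              length(x$features), x$C, x$gamma, x$weight_ratio))
  cat(sprintf("  GA fitness = %.4f (0.8 sens*spec + 0.2/k, inner %d-fold CV)\n",
              x$fitness, x$ga$inner_folds))
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  print(object)
  cat("  selected features:\n")
  cat(paste0("    ", object$features, collapse = "\n"), "\n")
  invisible(object)
}

#' @export
coef.ga_svm <- function(object, ...) {
  list(features = object$features, C = object$C, gamma = object$gamma,
       weight_ratio = object$weight_ratio)
}

#' Plot the GA fitness trace
#'
#' @param x a [ga_svm()] model.
#' @param ... passed to [plot()].
#' @export
plot.ga_svm <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "s",
       xlab = "generation", ylab = "best fitness",
       main = "GA fitness trace", ...)
  invisible(x)
}

#' Predict tumor grades with a fitted model
#'
#' @param object a [ga_svm()] model.
#' @param newdata matrix/data frame containing at least the selected feature
#'   columns.
#' @param type `"class"` for grade labels, `"score"` for decision values
#'   (larger = more high-grade).
#' @param ... unused.
#' @return factor of grades or numeric scores.
#' @export
predict.ga_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata, check.names = FALSE, optional = TRUE)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) stop("newdata lacks features: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  xm <- as.matrix(newdata[, object$features, drop = FALSE])
  sc <- svm_scores(object$model, xm)
  if (type == "class") sc$class else sc$score
}

#' Stratified tenfold cross-validation of an SVM configuration
#'
#' Splits the cases into `k` stratified folds, trains the class-weighted
#' RBF SVM on each training portion and predicts the held-out fold. The six
#' indices are computed from the confusion matrix pooled over all test
#' folds (whole-cohort fractions) and the A_Z from the pooled decision
#' values.
#'
#' @param x feature matrix/data frame (rows = cases).
#' @param y grade labels "low"/"high".
#' @param features character vector of selected feature columns (default:
#'   all columns).
#' @param C,gamma SVM hyperparameters.
#' @param weight_ratio penalty ratio (default: reciprocal class-count ratio).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold split.
#' @return object of class `cv_metrics`: list with `metrics` (the six
#'   indices, fractions), `confusion` (pooled [confusion_matrix()]),
#'   `scores`, `labels`, `folds`, `per_fold` data frame.
#' @export
tenfold_cv <- function(x, y, features = NULL, C = 1, gamma = NULL,
                       weight_ratio = NULL, k = 10L, seed = 1L) {
  x <- as.data.frame(x, check.names = FALSE, optional = TRUE)
  if (is.null(features)) features <- colnames(x)
  xm <- as.matrix(x[, features, drop = FALSE])
  if (anyNA(xm)) stop("feature matrix contains missing values", call. = FALSE)
  y <- as_grade(y)
  if (is.null(gamma)) gamma <- 1 / ncol(xm)
  if (is.null(weight_ratio)) {
    weight_ratio <- class_weight_ratio(sum(y == "low"), sum(y == "high"))
  }
  if (min(table(y)) < k) {
    stop("a fold would lose one class entirely: fewer cases per class than folds",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- stratified_folds(y, k)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2)) {
    stop("a fold lost one class entirely; too few cases for ", k, " folds",
         call. = FALSE)
  }
  pred <- factor(rep(NA_character_, length(y)), levels = grade_levels)
  score <- numeric(length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- svm_fit(xm[tr, , drop = FALSE], y[tr], C, gamma, weight_ratio)
    sc <- svm_scores(m, xm[!tr, , drop = FALSE])
    pred[!tr] <- sc$class
    score[!tr] <- sc$score
    cmf <- confusion_matrix(y[!tr], sc$class)
    per_fold[[f]] <- data.frame(fold = f, TP = cmf$TP, FP = cmf$FP,
                                TN = cmf$TN, FN = cmf$FN)
  }
  cm <- confusion_matrix(y, pred)
  met <- c(metrics_from_confusion(cm), A_Z = roc_auc(score, y))
  structure(list(metrics = met, confusion = cm, scores = score,
                 labels = y, folds = folds,
                 per_fold = do.call(rbind, per_fold)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat("Stratified cross-validation (pooled over test folds)\n")
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * m["accuracy"], 100 * m["sensitivity"],
              100 * m["specificity"]))
  cat(sprintf("  PPV %.2f%%  NPV %.2f%%  A_Z %.4f\n",
              100 * m["PPV"], 100 * m["NPV"], m["A_Z"]))
  invisible(x)
}
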