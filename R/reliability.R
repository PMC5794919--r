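# Reliability analysis of age estimates across acquisition conditions:
# signed differences to the original-image estimate (per rater), their mean
# (MSD) and sample standard deviation (SSD), intra-class correlation, and
# Bland-Altman limits of agreement between raters.

#' Construct / validate an age-estimate table
#'
#' Long-format records of (subject, rater, condition, age). At most one
#' record per (subject, rater, condition); the reference condition is
#' `"orig"`.
#'
#' @param df data.frame with columns `subject`, `rater`, `condition`,
#'   `age` (years).
#' @return The validated data.frame with class `age_estimate_table`.
#' @export
age_estimate_table <- function(df) {
  need <- c("subject", "rater", "condition", "age")
  if (!all(need %in% names(df)))
    stop("table must have columns subject, rater, condition, age")
  df <- df[, need]
  if (!is.numeric(df$age)) stop("age must be numeric (years)")
  key <- interaction(df$subject, df$rater, df$condition, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject, rater, condition) records")
  class(df) <- c("age_estimate_table", "data.frame")
  df
}

#' Signed differences to the original-image estimate
#'
#' For every non-reference record, the age estimated from accelerated data
#' minus the same rater's estimate from the original data:
#' `delta = age(condition) - age(orig)` per subject and rater. Reference
#' rows are excluded from the output.
#'
#' @param table An [age_estimate_table()].
#' @param reference Reference condition label (default `"orig"`).
#' @return data.frame (subject, rater, condition, delta).
#' @export
compute_deltas <- function(table, reference = "orig") {
  table <- age_estimate_table(table)
  ref <- table[table$condition == reference, ]
  sim <- table[table$condition != reference, ]
  key <- function(d) paste(d$subject, d$rater, sep = "\r")
  m <- match(key(sim), key(ref))
  if (anyNA(m)) {
    bad <- sim[which(is.na(m))[1], ]
    stop(sprintf("missing '%s' partner for subject %s, rater %s",
                 reference, bad$subject, bad$rater))
  }
  data.frame(subject = sim$subject, rater = sim$rater,
             condition = sim$condition, delta = sim$age - ref$age[m])
}

#' Mean and standard deviation of signed differences
#'
#' MSD is the arithmetic mean of the signed deltas (systematic offset);
#' SSD is their sample standard deviation (n - 1 denominator;
#' reliability). SSD requires at least two deltas and is `NA` otherwise.
#'
#' @param deltas Numeric vector of signed differences (years).
#' @return Named numeric vector `c(SSD = , MSD = )`.
#' @export
ssd_msd <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  c(SSD = if (length(deltas) >= 2) stats::sd(deltas) else NA_real_,
    MSD = mean(deltas))
}

#' Intra-class correlation for paired measurements
#'
#' Two-way model, single measures, from the standard mean-square
#' decomposition over subjects (rows) and raters/conditions (columns).
#' `"A"` (default) is absolute agreement, ICC(A,1); `"C"` is consistency,
#' ICC(C,1).
#'
#' @param a,b Numeric vectors of paired estimates over the same subjects.
#' @param type `"A"` or `"C"`.
#' @return ICC in `[-1, 1]`, or `NA` when the total variance is zero.
#' @export
icc <- function(a, b, type = c("A", "C")) {
  type <- match.arg(type)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  X <- cbind(a, b); k <- 2
  grand <- mean(X)
  if (sum((X - grand)^2) == 0) return(NA_real_)
  rm_ <- rowMeans(X); cm <- colMeans(X)
  MSR <- k * sum((rm_ - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  SSE <- sum((X - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- if (type == "A") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  }
  max(-1, min(1, val))
}

#' Bland-Altman bias and limits of agreement
#'
#' `bias = mean(a - b)`; `loa = 1.96 * sd(a - b)` reported as the
#' half-width around the bias (sample SD, n - 1). Per-pair means are
#' returned for plotting.
#'
#' @param a,b Numeric vectors of paired estimates.
#' @return List with `bias`, `loa`, `means`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  list(bias = mean(d), loa = 1.96 * stats::sd(d),
       means = (a + b) / 2, diffs = d)
}

#' Assemble the full reliability report
#'
#' Per (rater, condition): ICC against the rater's original-image
#' estimates (both absolute-agreement and consistency forms), SSD and MSD
#' of the signed differences. Per rater pair: ICC, Bland-Altman bias and
#' LOA over all subject-by-condition cells shared by both raters
#' (`pooling = "all"`, the default) or only non-reference cells
#' (`pooling = "sim"`).
#'
#' @param table An [age_estimate_table()].
#' @param reference Reference condition label (default `"orig"`).
#' @param pooling Pooling scope for inter-rater statistics.
#' @return Object of class `reliability_report`: list of data.frames
#'   `per_condition` and `inter_rater`.
#' @export
build_report <- function(table, reference = "orig",
                         pooling = c("all", "sim")) {
  pooling <- match.arg(pooling)
  table <- age_estimate_table(table)
  conds <- setdiff(unique(table$condition), reference)
  if (length(conds) < 1)
    stop("table must cover at least one non-reference condition")
  del <- compute_deltas(table, reference)

  per <- do.call(rbind, lapply(unique(table$rater), function(rt) {
    ref <- table[table$rater == rt & table$condition == reference, ]
    do.call(rbind, lapply(conds, function(cd) {
      sim <- table[table$rater == rt & table$condition == cd, ]
      if (nrow(sim) == 0) return(NULL)
      m <- match(sim$subject, ref$subject)
      dd <- del$delta[del$rater == rt & del$condition == cd]
      sm <- ssd_msd(dd)
      data.frame(rater = rt, condition = cd, n = nrow(sim),
                 ICC = if (nrow(sim) >= 3) icc(ref$age[m], sim$age, "A")
                       else NA_real_,
                 ICC_C = if (nrow(sim) >= 3) icc(ref$age[m], sim$age, "C")
                         else NA_real_,
                 SSD = sm[["SSD"]], MSD = sm[["MSD"]])
    }))
  }))

  raters <- unique(table$rater)
  pairs <- if (length(raters) >= 2) utils::combn(raters, 2) else NULL
  inter <- if (!is.null(pairs)) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      r1 <- pairs[1, i]; r2 <- pairs[2, i]
      t1 <- table[table$rater == r1, ]
      t2 <- table[table$rater == r2, ]
      if (pooling == "sim") {
        t1 <- t1[t1$condition != reference, ]
        t2 <- t2[t2$condition != reference, ]
      }
      key <- function(d) paste(d$subject, d$condition, sep = "\r")
      m <- match(key(t1), key(t2))
      ok <- !is.na(m)
      if (sum(ok) < 3) return(NULL)
      a <- t1$age[ok]; b <- t2$age[m[ok]]
      ba <- bland_altman(a, b)
      data.frame(rater_a = r1, rater_b = r2, n = length(a),
                 ICC = icc(a, b, "A"), ICC_C = icc(a, b, "C"),
                 bias = ba$bias, LOA = ba$loa)
    }))
  } else NULL

  structure(list(per_condition = per, inter_rater = inter,
                 reference = reference, pooling = pooling),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Reliability report (reference condition: ", x$reference, ")\n\n",
      sep = "")
  cat("Per rater x condition (vs ", x$reference, "):\n", sep = "")
  print(format(x$per_condition, digits = digits), row.names = FALSE)
  if (!is.null(x$inter_rater)) {
    cat("\nInter-rater agreement (pooling: ", x$pooling, "):\n", sep = "")
    print(format(x$inter_rater, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
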