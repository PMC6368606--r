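# Protein-family richness under subsampling, and its regression on the
# geochemical fluid-mixing proxy log10(SO4/Cl).
#
# Rarefaction draws proteins without replacement; the analytic companion
# is the classical hypergeometric expectation of the number of families
# observed in a random subsample.

#' Expected family richness in a random subsample (analytic rarefaction)
#'
#' For one metagenome with family counts \eqn{N_f} (total \eqn{N}), returns
#' the expected number of distinct families in a uniform random subsample
#' of `depth` proteins drawn without replacement:
#' \deqn{E[S] = \sum_f \left[1 - \binom{N - N_f}{d} / \binom{N}{d}\right]}
#' evaluated stably in log space.
#'
#' @param counts Non-negative integer vector of per-family counts.
#' @param depth Subsample size, between 0 and `sum(counts)`.
#' @return Expected number of distinct families (a real number).
#' @export
expected_richness <- function(counts, depth) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  n_total <- sum(counts)
  if (length(depth) != 1L || depth < 0) stop("depth must be a single value >= 0")
  if (depth > n_total) {
    stop(sprintf("depth (%d) exceeds total count (%d)", depth, n_total))
  }
  if (depth == 0) return(0)
  cc <- counts[counts > 0]
  # log C(N - N_f, d) - log C(N, d); lchoose() returns -Inf when d > N - N_f,
  # i.e. the family is certain to be observed
  p_missing <- exp(lchoose(n_total - cc, depth) - lchoose(n_total, depth))
  sum(1 - p_missing)
}

#' Monte-Carlo rarefaction of a family abundance table
#'
#' Subsamples each metagenome's proteins without replacement at each
#' requested depth, `n_reps` times, and reports the mean and standard
#' deviation of the number of distinct families observed.  Metagenomes
#' whose total protein count is below a requested depth are skipped for
#' that depth and reported in the `skipped` attribute.
#'
#' @param table Family abundance matrix (metagenomes x families), e.g. from
#'   [family_abundance()].
#' @param depths Integer vector of subsampling depths.
#' @param n_reps Number of Monte-Carlo replicates per (metagenome, depth).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Data frame with columns `metagenome_id`, `depth`,
#'   `mean_richness`, `sd_richness`, `n_reps`, `seed`; skipped
#'   (metagenome, depth) pairs in attribute `skipped`.
#' @export
rarefied_richness <- function(table, depths, n_reps = 100, seed = 1) {
  if (!is.matrix(table) || is.null(rownames(table))) {
    stop("table must be a matrix with metagenome row names")
  }
  if (any(table < 0)) stop("counts must be non-negative")
  if (length(n_reps) != 1L || n_reps <= 0) stop("n_reps must be a positive integer")
  depths <- as.integer(depths)
  if (any(depths < 0)) stop("depths must be non-negative")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  res <- list()
  skipped <- list()
  for (mg in rownames(table)) {
    counts <- table[mg, ]
    pool <- rep.int(seq_along(counts), counts)   # family index per protein
    n_total <- length(pool)
    for (d in depths) {
      if (d > n_total) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(metagenome_id = mg, depth = d, total = n_total)
        next
      }
      rich <- vapply(seq_len(n_reps), function(i) {
        length(unique(sample(pool, d, replace = FALSE)))
      }, numeric(1))
      res[[length(res) + 1L]] <- data.frame(
        metagenome_id = mg, depth = d,
        mean_richness = mean(rich),
        sd_richness = if (n_reps > 1L) stats::sd(rich) else 0,
        n_reps = n_reps, seed = seed)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(metagenome_id = character(), depth = integer(),
               mean_richness = numeric(), sd_richness = numeric(),
               n_reps = integer(), seed = integer())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Build a geochemistry record table
#'
#' Validates a per-spring geochemistry table and derives the fluid-mixing
#' proxy `log_ratio` = log10(sulfate / chloride).  High values indicate
#' vapor-phase (sulfide-derived sulfate) input mixed with meteoric water;
#' low values indicate deep chloride-rich reservoir input.
#'
#' @param geochem Data frame with columns `spring_id`, `sulfate` and
#'   `chloride` (mg/L); `pH` and `temperature` are carried through when
#'   present.
#' @return The table with a `log_ratio` column appended (NA where either
#'   concentration is missing or non-positive).
#' @export
geochem_records <- function(geochem) {
  stopifnot(is.data.frame(geochem),
            all(c("spring_id", "sulfate", "chloride") %in% names(geochem)))
  ok <- is.finite(geochem$sulfate) & is.finite(geochem$chloride) &
    geochem$sulfate > 0 & geochem$chloride > 0
  geochem$log_ratio <- ifelse(ok, log10(geochem$sulfate / geochem$chloride), NA_real_)
  geochem
}

#' Regress protein-family richness on the fluid-mixing proxy
#'
#' Ordinary least squares of per-spring richness (typically fixed-depth
#' subsampled family counts) on log10(SO4/Cl).  Springs missing either the
#' richness value or a defined log ratio are dropped listwise and counted.
#'
#' @param richness Data frame with columns `spring_id` and `richness`, or a
#'   named numeric vector.
#' @param geochem Geochemistry table; `log_ratio` is derived via
#'   [geochem_records()] if absent.
#' @return An object of class `diversity_fit`: list with `slope`,
#'   `intercept`, `r2`, `adj_r2` (\eqn{1 - (1-R^2)(n-1)/(n-2)}), `p_value`
#'   (F test), `n`, `n_dropped` and the underlying `lm` fit (`model`).
#' @export
fit_diversity_model <- function(richness, geochem) {
  if (is.numeric(richness) && !is.null(names(richness))) {
    richness <- data.frame(spring_id = names(richness), richness = unname(richness))
  }
  stopifnot(is.data.frame(richness),
            all(c("spring_id", "richness") %in% names(richness)))
  if (!"log_ratio" %in% names(geochem)) geochem <- geochem_records(geochem)
  df <- merge(richness, geochem[, c("spring_id", "log_ratio")], by = "spring_id")
  keep <- is.finite(df$richness) & is.finite(df$log_ratio)
  n_dropped <- nrow(richness) - sum(keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (n < 3L) stop(sprintf("need at least 3 springs with richness and geochemistry (have %d)", n))
  if (stats::var(df$log_ratio) == 0) stop("log_ratio has zero variance; regression design is degenerate")

  fit <- stats::lm(richness ~ log_ratio, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  r2 <- sm$r.squared
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                 p_value = p, n = n, n_dropped = n_dropped,
                 model = fit),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat(sprintf(
    "richness ~ log10(SO4/Cl): slope %.3f, intercept %.3f, adj R^2 = %.3f, p = %.3g, n = %d (%d dropped)\n",
    x$slope, x$intercept, x$adj_r2, x$p_value, x$n, x$n_dropped))
  invisible(x)
}
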