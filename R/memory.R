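#' Hit and false-alarm rates per stratum and memory class
#'
#' Computes recognition rates within strata (any grouping columns, e.g.
#' subject, affective category, stimulation, phase). Memory classes:
#'
#' * `overall`: hit = #(old trials answered "old") / #old; FA = #(new
#'   trials answered "old") / #new.
#' * `recollection`: numerators restricted to "old" responses at the top
#'   confidence anchor; denominators unchanged (all old / all new trials).
#' * `familiarity`: numerators restricted to sub-top "old" responses;
#'   denominators unchanged.
#'
#' With these shared denominators the split is additive:
#' recollection + familiarity counts (and hence Pr) equal the overall ones
#' per stratum, exactly.
#'
#' @param table a recognition tibble ([gen_recognition()] /
#'   [read_recognition()]): needs `truth`, `response`, `confidence` and the
#'   stratum columns.
#' @param strata character vector of grouping columns (default
#'   `"subject"`). Old-only columns (e.g. stimulation in a within design)
#'   may be NA on new trials; new trials are then crossed with every
#'   stratum level of the subject.
#' @param memory_class "overall", "recollection" or "familiarity".
#' @param top_anchor the recollection anchor; defaults by dialect (10 for
#'   eleven-point, 6 for six-point).
#' @return tibble: strata columns, memory_class, n_old, n_new, hits, fas,
#'   hit_rate, fa_rate, and `unstable` (fewer than 5 trials in the
#'   numerator class).
#' @export
memory_rates <- function(table, strata = "subject",
                         memory_class = c("overall", "recollection", "familiarity"),
                         top_anchor = NULL) {
  memory_class <- match.arg(memory_class)
  stopifnot(all(c("truth", "response", "confidence") %in% names(table)),
            all(strata %in% names(table)))
  if (is.null(top_anchor)) {
    top_anchor <- if ("dialect" %in% names(table) &&
                      table$dialect[1] == "six_point") 6L else 10L
  }
  in_class <- switch(memory_class,
    overall = rep(TRUE, nrow(table)),
    recollection = table$confidence == top_anchor,
    familiarity = table$confidence < top_anchor
  )
  old <- table[table$truth == "old", , drop = FALSE]
  new <- table[table$truth == "new", , drop = FALSE]
  ic_old <- in_class[table$truth == "old"]
  ic_new <- in_class[table$truth == "new"]

  old_tab <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(old, .ic = ic_old),
                    dplyr::across(dplyr::all_of(strata))),
    n_old = dplyr::n(),
    hits = sum(response == "old" & .ic),
    .groups = "drop"
  )
  # new trials have no old-only stratum labels; count them per subject-level
  # strata and cross with the remaining levels
  sub_strata <- strata[vapply(strata, function(s) !anyNA(new[[s]]), logical(1))]
  new_tab <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(new, .ic = ic_new),
                    dplyr::across(dplyr::all_of(sub_strata))),
    n_new = dplyr::n(),
    fas = sum(response == "old" & .ic),
    .groups = "drop"
  )
  out <- if (length(sub_strata)) {
    dplyr::left_join(old_tab, new_tab, by = sub_strata)
  } else {
    dplyr::cross_join(old_tab, new_tab)
  }
  if (any(is.na(out$n_new)) || any(out$n_old == 0)) {
    stop("a stratum has no old or no new trials")
  }
  dplyr::mutate(
    out,
    memory_class = memory_class,
    hit_rate = hits / n_old,
    fa_rate = fas / n_new,
    unstable = (hits < 5) | (fas < 5),
    .after = dplyr::all_of(strata)
  )
}

#' Discrimination index Pr
#'
#' `Pr = p(hit) - p(false alarm)`; positive values indicate old/new
#' discrimination above chance.
#'
#' @param hit,fa rates in [0, 1].
#' @return numeric vector.
#' @export
pr_index <- function(hit, fa) {
  stopifnot(all(hit >= 0 & hit <= 1), all(fa >= 0 & fa <= 1))
  hit - fa
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit) - z(fa)` with the standard extreme-rate correction: a rate
#' of 0 is replaced by 1/(2N) and a rate of 1 by 1 - 1/(2N), where N is
#' the relevant trial count, so d' is always finite.
#'
#' @param hit,fa rates in [0, 1].
#' @param n_old,n_new trial counts behind the hit and false-alarm rates.
#' @return numeric vector.
#' @export
d_prime <- function(hit, fa, n_old, n_new) {
  stopifnot(all(n_old > 0), all(n_new > 0))
  hit <- ifelse(hit <= 0, 1 / (2 * n_old), ifelse(hit >= 1, 1 - 1 / (2 * n_old), hit))
  fa <- ifelse(fa <= 0, 1 / (2 * n_new), ifelse(fa >= 1, 1 - 1 / (2 * n_new), fa))
  stats::qnorm(hit) - stats::qnorm(fa)
}

#' Tidy table of memory indices per stratum and memory class
#'
#' Combines [memory_rates()], [pr_index()] and [d_prime()] into one tidy
#' table: one row per stratum x memory class.
#'
#' @inheritParams memory_rates
#' @param classes memory classes to compute.
#' @return tibble with strata columns, memory_class, counts, rates, pr,
#'   d_prime.
#' @export
memory_indices <- function(table, strata = "subject",
                           classes = c("overall", "recollection", "familiarity"),
                           top_anchor = NULL) {
  purrr::map_dfr(classes, function(cl) {
    r <- memory_rates(table, strata, cl, top_anchor)
    dplyr::mutate(r,
      pr = pr_index(hit_rate, fa_rate),
      d_prime = d_prime(hit_rate, fa_rate, n_old, n_new)
    )
  })
}

#' Exclude subjects who cannot discriminate old from new
#'
#' Removes subjects whose overall Pr index (hit rate minus false-alarm
#' rate, over all their trials) is not greater than 0. The exclusion
#' report is attached as attribute `"exclusions"` and also retrievable via
#' [exclusion_report()].
#'
#' @param table a recognition tibble.
#' @return the filtered tibble (attribute `"exclusions"`: tibble of
#'   subject, pr for the removed subjects). Errors if no subject survives.
#' @export
exclude_poor_performers <- function(table) {
  ov <- memory_rates(table, strata = "subject", memory_class = "overall")
  ov$pr <- pr_index(ov$hit_rate, ov$fa_rate)
  excl <- ov[ov$pr <= 0, c("subject", "pr")]
  if (nrow(excl) == nrow(ov)) stop("all subjects have Pr <= 0")
  out <- table[!table$subject %in% excl$subject, , drop = FALSE]
  attr(out, "exclusions") <- tibble::as_tibble(excl)
  out
}

#' @rdname exclude_poor_performers
#' @export
exclusion_report <- function(table) {
  attr(table, "exclusions") %||% tibble::tibble(subject = character(), pr = numeric())
}

#' Write memory indices as tidy TSV
#'
#' @param indices a [memory_indices()] tibble.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_memory_indices <- function(indices, path) {
  utils::write.table(indices, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
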