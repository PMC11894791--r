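#' Build a study design with trial-level tables
#'
#' Emulates the two study designs:
#'
#' * **Study 1** (within-subject cross-over, default 30 subjects): a pool of
#'   240 unique images (120 neutral, 120 unpleasant) split into four
#'   counterbalanced sets of 60; two encoding sessions of 60 scenes each
#'   (one under taVNS, one under sham, order counterbalanced across
#'   subjects); retrieval one week later with all 120 encoded images
#'   intermixed with 120 new ones (240 retrieval rows per subject).
#'   Confidence dialect: eleven-point anchors 0-10.
#' * **Study 2** (mixed design, default 65 subjects): stimulation (taVNS vs
#'   sham) between subjects; one encoding session of 120 images (60 neutral,
#'   60 unpleasant) presented in alternating on/off stimulation half-cycles
#'   of exactly 4 images each; retrieval with the 120 old images plus 120
#'   new (240 rows). Confidence dialect: six-point anchors 1-6.
#'
#' Encoding orders are pseudorandomized with no more than two scenes of the
#' same affective category in a row, enforced by rejection resampling.
#'
#' @param study 1 or 2.
#' @param n_subjects number of subjects (defaults: 30 for Study 1, 65 for
#'   Study 2).
#' @param seed integer seed; tables are bit-identical across reruns with the
#'   same seed.
#' @return an object of class `study_design`: a list with `spec` (design
#'   parameters), `encoding` and `retrieval` tibbles. Encoding columns:
#'   subject, group, session, trial, item, category, stimulation, phase.
#'   Retrieval adds `truth` ("old"/"new").
#' @export
#' @examples
#' d <- build_design(1, seed = 1)
#' nrow(d$retrieval) / length(unique(d$retrieval$subject)) # 240 rows each
build_design <- function(study, n_subjects = NULL, seed = 1) {
  if (!study %in% c(1, 2)) stop("unknown study code: ", study)
  if (is.null(n_subjects)) n_subjects <- if (study == 1) 30L else 65L
  rng <- .child_rng(seed, "design")
  if (study == 1) .build_design1(n_subjects, rng) else .build_design2(n_subjects, rng)
}

# per-component RNG streams: one root seed, fixed offsets per stage
.rng_offsets <- c(design = 11L, behavior = 211L, epochs = 3011L, perm = 40011L)
.child_rng <- function(seed, component) {
  off <- .rng_offsets[[component]]
  (as.integer(seed) * 97L + off) %% .Machine$integer.max
}

# a category sequence with no run of >= 3 equal labels: sequential draws
# weighted by remaining counts, restarting on the (rare) dead ends
.constrained_order <- function(categories) {
  counts0 <- table(categories)
  cats <- names(counts0)
  repeat {
    counts <- stats::setNames(as.vector(counts0), cats)
    out <- character(length(categories))
    run_cat <- ""; run_len <- 0L; ok <- TRUE
    for (k in seq_along(out)) {
      allowed <- cats[counts > 0]
      if (run_len >= 2L) allowed <- setdiff(allowed, run_cat)
      if (!length(allowed)) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = counts[allowed])
      out[k] <- pick
      counts[pick] <- counts[pick] - 1L
      if (identical(pick, run_cat)) run_len <- run_len + 1L
      else { run_cat <- pick; run_len <- 1L }
    }
    if (ok) return(out)
  }
}

.build_design1 <- function(n_subjects, rng_seed) {
  set.seed(rng_seed)
  # 240 items in four sets of 60 (30 neutral + 30 unpleasant each)
  items <- tibble::tibble(
    item = sprintf("img%03d", 1:240),
    category = rep(rep(c("neutral", "unpleasant"), each = 30), times = 4),
    set = rep(1:4, each = 60)
  )
  enc <- list(); ret <- list()
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%03d", s)
    # counterbalance: which sets are encoded under taVNS / sham / left new,
    # and the session order of the two stimulation days
    sets <- sample(1:4)
    order_tavns_first <- (s %% 2) == 1
    stim_by_session <- if (order_tavns_first) c("taVNS", "sham") else c("sham", "taVNS")
    set_by_session <- sets[1:2]
    for (sess in 1:2) {
      pool <- items[items$set == set_by_session[sess], ]
      ord <- .constrained_order(pool$category)
      # lay the items down to match the constrained category order
      idx <- integer(nrow(pool))
      left <- lapply(split(seq_len(nrow(pool)), pool$category), sample)
      for (k in seq_along(ord)) {
        idx[k] <- left[[ord[k]]][1]
        left[[ord[k]]] <- left[[ord[k]]][-1]
      }
      pool <- pool[idx, ]
      enc[[length(enc) + 1]] <- tibble::tibble(
        subject = subj, group = NA_character_, session = sess,
        trial = seq_len(nrow(pool)), item = pool$item, category = pool$category,
        stimulation = stim_by_session[sess], phase = NA_character_
      )
    }
    old <- items[items$set %in% set_by_session, ]
    old$stimulation <- stim_by_session[match(old$set, set_by_session)]
    new <- items[items$set %in% sets[3:4], ]
    rt <- tibble::tibble(
      subject = subj, group = NA_character_, session = 3L,
      item = c(old$item, new$item),
      category = c(old$category, new$category),
      stimulation = c(old$stimulation, rep(NA_character_, nrow(new))),
      phase = NA_character_,
      truth = rep(c("old", "new"), c(nrow(old), nrow(new)))
    )
    rt <- rt[sample(nrow(rt)), ]
    rt$trial <- seq_len(nrow(rt))
    ret[[length(ret) + 1]] <- rt
  }
  structure(
    list(
      spec = list(
        study = 1L, n_subjects = n_subjects, n_old_per_cell = 30L, n_new = 120L,
        cells = c("neutral.taVNS", "neutral.sham", "unpleasant.taVNS", "unpleasant.sham"),
        confidence_dialect = "eleven_point", seed = rng_seed
      ),
      encoding = dplyr::bind_rows(enc),
      retrieval = dplyr::bind_rows(ret)[, c("subject", "group", "session", "trial",
                                            "item", "category", "stimulation",
                                            "phase", "truth")]
    ),
    class = "study_design"
  )
}

# Study 2 encoding: categories constrained as above, phase tiled in runs of 4
.build_design2 <- function(n_subjects, rng_seed) {
  set.seed(rng_seed)
  items <- tibble::tibble(
    item = sprintf("img%03d", 1:240),
    category = rep(c("neutral", "unpleasant"), each = 120)
  )
  # balanced random group assignment (sizes differ by at most 1)
  groups <- sample(rep(c("taVNS", "sham"), length.out = n_subjects))
  enc <- list(); ret <- list()
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%03d", s)
    old_items <- dplyr::bind_rows(
      items[items$category == "neutral", ][sample(120, 60), ],
      items[items$category == "unpleasant", ][sample(120, 60), ]
    )
    ord <- .constrained_order(old_items$category)
    left <- lapply(split(seq_len(nrow(old_items)), old_items$category), sample)
    idx <- integer(120)
    for (k in seq_len(120)) {
      idx[k] <- left[[ord[k]]][1]
      left[[ord[k]]] <- left[[ord[k]]][-1]
    }
    old_items <- old_items[idx, ]
    phase <- rep(rep(c("on", "off"), each = 4), length.out = 120)
    enc[[length(enc) + 1]] <- tibble::tibble(
      subject = subj, group = groups[s], session = 1L, trial = 1:120,
      item = old_items$item, category = old_items$category,
      stimulation = groups[s], phase = phase
    )
    new_items <- dplyr::anti_join(items, old_items, by = c("item", "category"))
    rt <- tibble::tibble(
      subject = subj, group = groups[s], session = 2L,
      item = c(old_items$item, new_items$item),
      category = c(old_items$category, new_items$category),
      stimulation = groups[s],
      phase = c(phase, rep(NA_character_, nrow(new_items))),
      truth = rep(c("old", "new"), c(120L, nrow(new_items)))
    )
    rt <- rt[sample(nrow(rt)), ]
    rt$trial <- seq_len(nrow(rt))
    ret[[length(ret) + 1]] <- rt
  }
  structure(
    list(
      spec = list(
        study = 2L, n_subjects = n_subjects, n_old_per_cell = 30L, n_new = 120L,
        cells = c("neutral.on", "neutral.off", "unpleasant.on", "unpleasant.off"),
        groups = c("taVNS", "sham"), block_size = 4L,
        confidence_dialect = "six_point", seed = rng_seed
      ),
      encoding = dplyr::bind_rows(enc),
      retrieval = dplyr::bind_rows(ret)[, c("subject", "group", "session", "trial",
                                            "item", "category", "stimulation",
                                            "phase", "truth")]
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> Study %d: %d subjects, %d encoding + %d retrieval rows (%s dialect)\n",
    x$spec$study, x$spec$n_subjects, nrow(x$encoding), nrow(x$retrieval),
    x$spec$confidence_dialect
  ))
  invisible(x)
}
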