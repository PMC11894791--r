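#' Dual-process recognition-behavior generator configuration
#'
#' The generative model follows dual-process signal detection: an old item
#' is *recollected* with per-cell probability `R`, in which case the
#' response is "old" at the top confidence anchor; otherwise a familiarity
#' strength `x ~ Normal(d_fam, 1)` (standard-normal units) is binned
#' through strictly increasing criteria into a confidence anchor. New items
#' draw `x ~ Normal(0, 1)` (and are recollected with probability
#' `false_rec`, default 0).
#'
#' Dialects:
#' * `six_point` (anchors 1-6): five criteria bin strength into anchors
#'   1-6; responses with anchor >= 4 are "old".
#' * `eleven_point` (anchors 0-10): ten criteria bin strength into an
#'   oldness axis 0-10; responses with anchor >= 6 are "old". The stored
#'   confidence equals the anchor for "old" responses (so recollection is
#'   confidence 10) and `10 - anchor` for "new" responses, mimicking the
#'   separate old/new + confidence two-question format.
#'
#' Default criteria place the old/new decision boundary at 0.75 on the
#' strength axis; with `d_fam` near 1 this yields hit and false-alarm rates
#' in the range typically seen in week-delayed scene recognition.
#'
#' @param dialect "eleven_point" or "six_point".
#' @param R named numeric vector of per-cell recollection probabilities
#'   (names are design cells `category.stimulation` or a single unnamed
#'   value recycled to all cells).
#' @param d_fam named numeric vector of per-cell familiarity means, same
#'   naming convention as `R`.
#' @param criteria strictly increasing numeric vector: 10 values for
#'   `eleven_point`, 5 for `six_point`. `NULL` selects the dialect default.
#' @param false_rec probability that a new item is falsely recollected.
#' @return an object of class `behavior_config`.
#' @export
behavior_config <- function(dialect = c("eleven_point", "six_point"),
                            R = 0.25, d_fam = 1.0, criteria = NULL,
                            false_rec = 0) {
  dialect <- match.arg(dialect)
  if (is.null(criteria)) {
    criteria <- switch(dialect,
      six_point = 0.75 + seq(-1.5, 1.5, by = 0.75),
      eleven_point = 0.75 + seq(-2.25, 2.25, by = 0.5)
    )
  }
  n_crit <- switch(dialect, six_point = 5L, eleven_point = 10L)
  if (length(criteria) != n_crit) {
    stop(sprintf("dialect '%s' needs %d criteria, got %d",
                 dialect, n_crit, length(criteria)))
  }
  if (any(diff(criteria) <= 0)) stop("criteria must be strictly increasing")
  stopifnot(all(R >= 0 & R <= 1), false_rec >= 0, false_rec <= 1)
  structure(
    list(dialect = dialect, R = R, d_fam = d_fam, criteria = criteria,
         false_rec = false_rec),
    class = "behavior_config"
  )
}

.cell_param <- function(par, cell) {
  if (is.null(names(par))) return(par[[1]])
  if (cell %in% names(par)) return(par[[cell]])
  if ("default" %in% names(par)) return(par[["default"]])
  stop("no parameter value for cell '", cell, "'")
}

# strength -> anchor via the ordered criteria (anchor base differs by dialect)
.bin_strength <- function(x, criteria, first_anchor) {
  findInterval(x, criteria) + first_anchor
}

#' Generate trial-level recognition behavior
#'
#' Draws, for every retrieval trial of a design, an old/new response and a
#' confidence anchor from the dual-process model in [behavior_config()].
#' Old-trial cells are keyed `category.stimulation` (Study 1) or
#' `category.phase` within stimulation group (Study 2); both the generic
#' cell key and per-factor columns are carried on the output.
#'
#' @param design a [build_design()] result.
#' @param cfg a [behavior_config()]; its dialect must match the design's.
#' @param seed integer seed.
#' @return a `RecognitionTable` tibble: subject, group, stimulation, phase,
#'   category, truth, response, confidence.
#' @export
#' @examples
#' d <- build_design(2, n_subjects = 4, seed = 1)
#' b <- gen_recognition(d, behavior_config("six_point"), seed = 1)
#' table(b$truth, b$response)
gen_recognition <- function(design, cfg, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "behavior_config"))
  if (cfg$dialect != design$spec$confidence_dialect) {
    stop("config dialect does not match the design's confidence dialect")
  }
  set.seed(.child_rng(seed, "behavior"))
  tab <- design$retrieval
  study <- design$spec$study
  cell_of <- function(i) {
    if (tab$truth[i] == "new") return("new")
    if (study == 1) paste(tab$category[i], tab$stimulation[i], sep = ".")
    else paste(tab$category[i], tab$phase[i], sep = ".")
  }
  n <- nrow(tab)
  first_anchor <- if (cfg$dialect == "six_point") 1L else 0L
  top_anchor <- if (cfg$dialect == "six_point") 6L else 10L
  old_cut <- if (cfg$dialect == "six_point") 4L else 6L

  cells <- vapply(seq_len(n), cell_of, character(1))
  rec_p <- ifelse(cells == "new", cfg$false_rec,
                  vapply(cells, function(cl) .cell_param(cfg$R, cl), numeric(1)))
  mu <- ifelse(cells == "new", 0,
               vapply(cells, function(cl) .cell_param(cfg$d_fam, cl), numeric(1)))
  recollected <- stats::runif(n) < rec_p
  x <- stats::rnorm(n, mean = mu, sd = 1)
  anchor <- .bin_strength(x, cfg$criteria, first_anchor)
  anchor[recollected] <- top_anchor

  if (cfg$dialect == "six_point") {
    response <- ifelse(anchor >= old_cut, "old", "new")
    confidence <- anchor
  } else {
    response <- ifelse(anchor >= old_cut, "old", "new")
    confidence <- ifelse(response == "old", anchor, 10L - anchor)
  }
  tibble::tibble(
    subject = tab$subject, group = tab$group, stimulation = tab$stimulation,
    phase = tab$phase, category = tab$category, truth = tab$truth,
    response = response, confidence = as.integer(confidence),
    dialect = cfg$dialect
  )
}

#' Write / read a recognition table as TSV
#'
#' The dialect is recorded in a `# dialect:` header comment, as the column
#' set alone does not identify the confidence scale.
#'
#' @param table a recognition tibble from [gen_recognition()].
#' @param path file path.
#' @return `read_recognition` returns the tibble; `write_recognition` its
#'   path, invisibly.
#' @export
write_recognition <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dialect: ", table$dialect[1]), con)
  utils::write.table(table[setdiff(names(table), "dialect")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recognition
#' @export
read_recognition <- function(path) {
  first <- readLines(path, n = 1)
  dialect <- sub("^# dialect: *", "", first)
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  out$dialect <- dialect
  tibble::as_tibble(out)
}
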