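#' Sleep stage taxonomy
#'
#' The package uses the Rechtschaffen--Kales (R&K) stage set throughout:
#' wake (`W`), the four NREM stages `S1`--`S4`, and `REM`. Two further
#' tokens occur in scored recordings but never reach a model: `MOVEMENT`
#' (movement time, scored `M`) and `UNSCORED` (`?`, `X`, or any token the
#' scorer left ambiguous).
#'
#' @return Character vector of the eight recognised stage labels, the six
#'   scoreable stages first.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() {
  c("W", "S1", "S2", "S3", "S4", "REM", "MOVEMENT", "UNSCORED")
}

#' The six scoreable stages (no MOVEMENT/UNSCORED)
#' @return Character vector `c("W","S1","S2","S3","S4","REM")`.
#' @export
scoreable_stages <- function() stage_levels()[1:6]

#' Parse raw stage tokens into stage labels
#'
#' Maps the stage strings found in hypnogram files onto the closed label
#' set of [stage_levels()]. Matching is case-insensitive and strips the
#' `"Sleep stage "` prefix used by EDF+ annotation files. Numeric tokens
#' `1`--`4` denote `S1`--`S4`, `R` denotes `REM`, `M` movement time.
#' Anything unrecognised (including `"?"` and `"X"`) becomes `UNSCORED`.
#'
#' @param tokens character vector of raw stage tokens.
#' @return Factor with levels [stage_levels()].
#' @export
#' @examples
#' parse_stage(c("Sleep stage W", "Sleep stage 1", "R", "m", "?", "X"))
parse_stage <- function(tokens) {
  tok <- trimws(tokens)
  tok <- sub("^sleep stage ", "", tok, ignore.case = TRUE)
  tok <- toupper(tok)
  map <- c(
    "W" = "W", "WAKE" = "W",
    "1" = "S1", "S1" = "S1",
    "2" = "S2", "S2" = "S2",
    "3" = "S3", "S3" = "S3",
    "4" = "S4", "S4" = "S4",
    "R" = "REM", "REM" = "REM",
    "M" = "MOVEMENT", "MOVEMENT" = "MOVEMENT", "MOVEMENT TIME" = "MOVEMENT"
  )
  out <- unname(map[tok])
  out[is.na(out)] <- "UNSCORED"
  factor(out, levels = stage_levels())
}

as_stage <- function(labels) {
  if (is.factor(labels) && identical(levels(labels), stage_levels())) {
    return(labels)
  }
  parse_stage(as.character(labels))
}

#' Remove ambiguous epochs
#'
#' Scored recordings contain epochs marked as movement time (`M`) or left
#' unscored (`?`, `X`, ...). These carry no stage information and are
#' eliminated before modelling. Order is preserved.
#'
#' @param labels vector (character or factor) of stage labels.
#' @return List with `indices` (strictly increasing positions of the kept
#'   epochs in the input, 1-based) and `labels` (the kept labels as a
#'   factor over [stage_levels()]).
#' @export
#' @examples
#' filter_ambiguous(c("W", "?", "S2"))
filter_ambiguous <- function(labels) {
  labels <- as_stage(labels)
  keep <- which(!labels %in% c("MOVEMENT", "UNSCORED"))
  list(indices = keep, labels = labels[keep])
}

# Table of stage -> class-name groupings for each scheme (W always first,
# hence class index 0 in the 0-based confusion-matrix layout).
.scheme_table <- list(
  `6` = c(W = "W", S1 = "S1", S2 = "S2", S3 = "S3", S4 = "S4", REM = "REM"),
  `5` = c(W = "W", S1 = "S1", S2 = "S2", S3 = "SWS", S4 = "SWS", REM = "REM"),
  `4` = c(W = "W", S1 = "S1+S2", S2 = "S1+S2", S3 = "SWS", S4 = "SWS", REM = "REM"),
  `3` = c(W = "W", S1 = "NREM", S2 = "NREM", S3 = "NREM", S4 = "NREM", REM = "REM"),
  `2` = c(W = "W", S1 = "Sleep", S2 = "Sleep", S3 = "Sleep", S4 = "Sleep", REM = "Sleep")
)

#' Build a class-merging scheme
#'
#' The six R&K stages are merged into 2--6 classes. The groupings are:
#' \describe{
#'   \item{6}{W | S1 | S2 | S3 | S4 | REM (identity)}
#'   \item{5}{W | S1 | S2 | SWS (S3+S4) | REM}
#'   \item{4}{W | S1+S2 | SWS (S3+S4) | REM}
#'   \item{3}{W | NREM (S1+S2+S3+S4) | REM}
#'   \item{2}{W | Sleep (S1+S2+S3+S4+REM)}
#' }
#' Class indices follow this left-to-right order, so wake is always class
#' 0 and the confusion-matrix layout is stable across schemes.
#'
#' @param n_classes integer in `2:6`.
#' @return An object of class `"class_scheme"`: a list with `n_classes`,
#'   `class_names` (ordered), and `map`, a named integer vector giving the
#'   0-based class index of each scoreable stage.
#' @export
#' @examples
#' make_scheme(5)$map          # S3 and S4 share the SWS class
#' make_scheme(2)$class_names
make_scheme <- function(n_classes) {
  if (length(n_classes) != 1L || !n_classes %in% 2:6) {
    stop("`n_classes` must be a single integer in 2:6", call. = FALSE)
  }
  groups <- .scheme_table[[as.character(n_classes)]]
  class_names <- unique(unname(groups))
  map <- match(groups, class_names) - 1L
  names(map) <- names(groups)
  structure(
    list(n_classes = as.integer(n_classes), class_names = class_names, map = map),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme> %d classes: %s\n", x$n_classes,
              paste(x$class_names, collapse = " | ")))
  for (cn in x$class_names) {
    stages <- names(x$map)[x$class_names[x$map + 1L] == cn]
    cat(sprintf("  %-6s <- %s\n", cn, paste(stages, collapse = " + ")))
  }
  invisible(x)
}

#' Apply a class scheme to stage labels
#'
#' @param scheme a `"class_scheme"` from [make_scheme()].
#' @param labels stage labels (character or factor); must contain no
#'   `MOVEMENT`/`UNSCORED` entries (see [filter_ambiguous()]).
#' @return Factor over the scheme's class names.
#' @export
apply_scheme <- function(scheme, labels) {
  stopifnot(inherits(scheme, "class_scheme"))
  labels <- as_stage(labels)
  if (any(labels %in% c("MOVEMENT", "UNSCORED"))) {
    stop("labels contain MOVEMENT/UNSCORED epochs; run filter_ambiguous() first",
         call. = FALSE)
  }
  idx <- scheme$map[as.character(labels)]
  factor(scheme$class_names[idx + 1L], levels = scheme$class_names)
}

#' Tabulate the stage composition of a recording
#'
#' Counts each stage and expresses it as a percentage of the total,
#' truncated (not rounded) to two decimals -- the convention used in the
#' composition tables of the sleep-edf/sleep-edfx literature, e.g.
#' 604 of 15,188 epochs prints as 3.97\%.
#'
#' @param labels stage labels (character or factor).
#' @return Data frame with columns `stage`, `count`, `percent`. Stages
#'   with zero count are dropped; an empty input gives zero rows.
#' @export
#' @examples
#' class_distribution(rep(c("W", "S2"), c(3, 1)))
class_distribution <- function(labels) {
  labels <- as_stage(labels)
  if (length(labels) == 0L) {
    return(data.frame(stage = character(), count = integer(), percent = numeric()))
  }
  tab <- table(labels)
  tab <- tab[tab > 0L]
  pct <- floor(1e4 * as.integer(tab) / length(labels)) / 100
  data.frame(
    stage = names(tab),
    count = as.integer(tab),
    percent = pct,
    row.names = NULL
  )
}
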