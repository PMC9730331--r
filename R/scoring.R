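#' Size-based PI-RADS v2.1 scoring rule
#'
#' Maps a lesion's maximum diameter to a score in 2..5 through three
#' strictly increasing diameter cut-points, right-closed at every
#' boundary (`d >= t` promotes, matching the ">= 1.5 cm" convention at
#' the 4/5 boundary). The printed guideline fixes only the 4/5 cutoff
#' (1.5 cm) and the clinical-significance volume bound (0.5 cc); the
#' lower cut-points default to midpoints between adjacent per-score mean
#' diameters of the ellipse-fit measurement table and must be reviewed
#' for any other cohort.
#'
#' @param t23,t34,t45 diameter cut-points in cm, `0 < t23 < t34 < t45`.
#' @param v_sig clinical-significance volume threshold in cc (flag is
#'   `volume > v_sig`, strict).
#' @param volume_override if `TRUE`, a lesion scored 3 with
#'   `volume > v_sig` is promoted to 4 (off by default; the size ladder
#'   is diameter-only).
#' @return list of class `score_rule`.
#' @export
score_rule <- function(t23 = 0.57, t34 = 0.82, t45 = 1.5, v_sig = 0.5,
                       volume_override = FALSE) {
  if (!(0 < t23 && t23 < t34 && t34 < t45))
    stop("cut-points must satisfy 0 < t23 < t34 < t45")
  if (v_sig <= 0) stop("v_sig must be > 0")
  structure(list(t23 = t23, t34 = t34, t45 = t45, v_sig = v_sig,
                 volume_override = isTRUE(volume_override)),
            class = "score_rule")
}

#' Assign a PI-RADS score and clinical-significance flag to one lesion
#'
#' @param m a [measure_lesion()] result, or a list/row with
#'   `max_diameter_cm` and `volume_cc`.
#' @param rule a [score_rule()].
#' @return list of class `score_record` with `max_diameter_cm`,
#'   `volume_cc`, `score` (integer 2..5) and `clinically_significant`
#'   (`volume > v_sig` or `score >= 4`).
#' @export
assign_score <- function(m, rule = score_rule()) {
  d <- m$max_diameter_cm; v <- m$volume_cc
  if (!is.finite(d) || !is.finite(v) || d <= 0 || v <= 0)
    stop("measurements must be positive and finite")
  score <- if (d >= rule$t45) 5L else if (d >= rule$t34) 4L
           else if (d >= rule$t23) 3L else 2L
  if (rule$volume_override && score == 3L && v > rule$v_sig) score <- 4L
  structure(list(max_diameter_cm = d, volume_cc = v, score = score,
                 clinically_significant = v > rule$v_sig || score >= 4L),
            class = "score_record")
}

#' @export
print.score_record <- function(x, ...) {
  cat(sprintf("score_record: d = %.2f cm, v = %.2f cc -> PI-RADS %d%s\n",
              x$max_diameter_cm, x$volume_cc, x$score,
              if (x$clinically_significant) " (clinically significant)"
              else ""))
  invisible(x)
}

#' Score a cohort of lesion measurements
#'
#' @param measurements list of [measure_lesion()] results (or of lists
#'   with `max_diameter_cm` / `volume_cc`), or a data.frame with columns
#'   `max_diameter_cm` (or `diameter_cm`) and `volume_cc`.
#' @param rule a [score_rule()].
#' @return list of class `score_table`: `scores` (data.frame `lesion`,
#'   `max_diameter_cm`, `volume_cc`, `score`, `clinically_significant`)
#'   and `summary` (per observed score: n, mean and SD of diameter and
#'   volume; scores with no lesions are absent).
#' @export
score_cohort <- function(measurements, rule = score_rule()) {
  if (is.data.frame(measurements)) {
    dcol <- intersect(c("max_diameter_cm", "diameter_cm"),
                      names(measurements))[1]
    if (is.na(dcol) || !"volume_cc" %in% names(measurements))
      stop("need diameter and volume columns")
    measurements <- lapply(seq_len(nrow(measurements)), function(i)
      list(max_diameter_cm = measurements[[dcol]][i],
           volume_cc = measurements$volume_cc[i]))
  }
  if (length(measurements) < 1) stop("need at least one measurement")
  recs <- lapply(measurements, assign_score, rule = rule)
  scores <- data.frame(
    lesion = seq_along(recs),
    max_diameter_cm = vapply(recs, `[[`, numeric(1), "max_diameter_cm"),
    volume_cc = vapply(recs, `[[`, numeric(1), "volume_cc"),
    score = vapply(recs, `[[`, integer(1), "score"),
    clinically_significant = vapply(recs, `[[`, logical(1),
                                    "clinically_significant"))
  sm <- do.call(rbind, lapply(sort(unique(scores$score)), function(s) {
    g <- scores[scores$score == s, ]
    data.frame(score = s, n = nrow(g),
               diameter_mean = mean(g$max_diameter_cm),
               diameter_sd = stats::sd(g$max_diameter_cm),
               volume_mean = mean(g$volume_cc),
               volume_sd = stats::sd(g$volume_cc))
  }))
  structure(list(scores = scores, summary = sm, rule = rule),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", nrow(x$scores), "lesion(s)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
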