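#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a similarity result
#' @param x a [similarity_result()].
#' @param ... unused.
#' @return one-row tibble with `st`, `ct`, `combo`.
#' @method tidy similarity_result
#' @export
tidy.similarity_result <- function(x, ...) {
  tibble(st = x$st, ct = x$ct, combo = x$combo)
}

#' Tidy a conformer model
#' @param x a [conformer_model()].
#' @param ... unused.
#' @return tibble with one row per conformer: `local_id`, `energy`,
#'   `diverse_rank`, `gid`.
#' @method tidy conformer_model
#' @export
tidy.conformer_model <- function(x, ...) {
  lid <- vapply(x$conformers, function(cf) cf$local_id, integer(1))
  tibble(
    local_id = lid,
    energy = vapply(x$conformers, function(cf) cf$energy, numeric(1)),
    diverse_rank = match(seq_along(lid), x$diverse_order),
    gid = vapply(x$conformers, function(cf) conformer_gid(x$molecule, cf),
                 character(1))
  )
}

#' One-row summary of a conformer model
#' @param x a [conformer_model()].
#' @param params a [shape_params()] for the default-conformer volume.
#' @param ... unused.
#' @return one-row tibble: `record_id`, `n_conformers`, `sampling_rmsd`,
#'   `default_volume`.
#' @method glance conformer_model
#' @export
glance.conformer_model <- function(x, params = shape_params(), ...) {
  default <- x$conformers[[x$diverse_order[1]]]
  tibble(record_id = x$molecule$record_id,
         n_conformers = length(x$conformers),
         sampling_rmsd = x$sampling_rmsd,
         default_volume = self_volume(default, params, x$molecule))
}

#' Tidy a feature set
#' @param x a `feature_set`.
#' @param ... unused.
#' @return tibble with `type`, `n_members`, `x`, `y`, `z`.
#' @method tidy feature_set
#' @export
tidy.feature_set <- function(x, ...) {
  f <- x$features
  tibble(type = f$type, n_members = lengths(f$members),
         x = f$position[, 1], y = f$position[, 2], z = f$position[, 3])
}

#' Heatmap of a pairwise score matrix
#'
#' @param object a `score_matrix` from [score_matrix()].
#' @param score which matrix to draw: `"combo"`, `"st"` or `"ct"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot score_matrix
#' @export
autoplot.score_matrix <- function(object, score = c("combo", "st", "ct"),
                                  ...) {
  score <- match.arg(score)
  m <- object[[score]]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = toupper(score)) +
    ggplot2::labs(x = "compound", y = "compound") +
    ggplot2::theme_minimal()
}

#' Distribution plot of a random-similarity study
#'
#' @param object a `random_similarity_stats` tibble from
#'   [random_similarity_study()].
#' @param ... unused.
#' @return a ggplot object showing mean +/- sd and the mu + 2 sigma
#'   threshold per score.
#' @method autoplot random_similarity_stats
#' @export
autoplot.random_similarity_stats <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$threshold), shape = 4,
                        size = 3) +
    ggplot2::labs(x = NULL, y = "similarity",
                  caption = "cross = mean + 2 sd threshold") +
    ggplot2::theme_minimal()
}
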