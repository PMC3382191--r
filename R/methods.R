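# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' @export
tidy.pharmacophore <- function(x, ...) {
  bind_rows(
    mutate(x$features, element = "feature", radius = .data$tolerance) |>
      select("element", "label", "kind", "x", "y", "z", "radius",
             "essential"),
    mutate(x$volumes, element = "volume", label = .data$provenance,
           kind = .data$class, essential = NA) |>
      select("element", "label", "kind", "x", "y", "z", "radius",
             "essential"))
}

#' @export
glance.pharmacophore <- function(x, ...) {
  tibble(n_features = nrow(x$features),
         n_essential = sum(x$features$essential),
         n_volumes = nrow(x$volumes),
         r_aliphatic = x$radius_map[["aliphatic"]],
         r_aromatic = x$radius_map[["aromatic"]],
         r_polar = x$radius_map[["polar"]],
         ring_radius = x$ring_radius)
}

#' @export
tidy.screen_result <- function(x, ...) as_tibble(x)

#' @export
glance.screen_result <- function(x, active_set = "full",
                                 inactive_set = "inactive", ...) {
  has_both <- any(x$activity %in% active_set) &&
    any(x$activity %in% inactive_set)
  sc <- if (has_both) discrimination_score(x, active_set, inactive_set)
        else list(active_hit_fraction = NA_real_,
                  inactive_hit_fraction = NA_real_, score = NA_real_)
  tibble(n_ligands = nrow(x), n_hit = sum(x$n_hits > 0),
         active_hit_fraction = sc$active_hit_fraction,
         inactive_hit_fraction = sc$inactive_hit_fraction,
         score = sc$score)
}

#' @export
tidy.pocket_report <- function(x, ...) as_tibble(x$residues)

#' @export
glance.pocket_report <- function(x, ...) {
  tibble(n_residues = x$n_residues, volume = x$volume,
         n_nonconserved = x$n_nonconserved)
}

#' Plot a pharmacophore model projection
#'
#' 2D projection (xy by default) of feature tolerance spheres and
#' excluded volumes, drawn to scale.
#'
#' @param object A [pharmacophore()].
#' @param axes Which coordinates to project onto (two of `"x"`, `"y"`,
#'   `"z"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pharmacophore <- function(object, axes = c("x", "y"), ...) {
  td <- tidy(object)
  td$u <- td[[axes[1]]]
  td$v <- td[[axes[2]]]
  circle <- function(u, v, r, grp, element) {
    t <- seq(0, 2 * pi, length.out = 60)
    tibble(u = u + r * cos(t), v = v + r * sin(t), grp = grp,
           element = element)
  }
  circles <- bind_rows(pmap(list(td$u, td$v, td$radius, seq_len(nrow(td)),
                                 td$element), circle))
  ggplot2::ggplot(circles,
                  ggplot2::aes(x = .data$u, y = .data$v, group = .data$grp,
                               colour = .data$element)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(axes[1], " (Å)"),
                  y = paste0(axes[2], " (Å)"),
                  colour = NULL,
                  title = "Pharmacophore features and excluded volumes") +
    ggplot2::theme_minimal()
}

#' Plot a screen result
#'
#' Hit fraction (`n_hits / n_conformers`) per ligand, coloured by activity
#' class.
#'
#' @param object A `screen_result` tibble from [screen_library()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  d <- mutate(as_tibble(object),
              hit_fraction = ifelse(.data$n_conformers > 0,
                                    .data$n_hits / .data$n_conformers, 0))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$ligand_id,
                                                     .data$hit_fraction),
                                  y = .data$hit_fraction,
                                  fill = .data$activity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "conformer hit fraction", fill = "activity") +
    ggplot2::theme_minimal()
}
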