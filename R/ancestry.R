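#' Node-distance ancestry of the leaves of a rooted tree
#'
#' For every leaf, the number of internal nodes `d` on the path from
#' the root to the leaf is counted and rescaled to
#' `nd = (d - d_min) / (d_max - d_min)`, so the basal-most leaf scores
#' exactly 0 and the deepest leaves score 1.  When a leaf attaches
#' directly at the root (`d_min = 1`, the usual case for trees rooted
#' through a hypothetical ancestor) this is `(d - 1) / (d_max - 1)`.
#' On a tree of substructures nd is a relative age: 0 marks the first
#' structural component accreted by the evolving molecule, 1 the most
#' recent.  A degenerate tree with all leaves at one depth (a star)
#' returns nd = 0 for every leaf.
#'
#' @param tree a rooted `phylo` (may contain polytomies, e.g. a strict
#'   consensus; each polytomy node counts once).  A strict consensus of
#'   rooted trees whose basal node is a polytomy is accepted as rooted
#'   (it carries a `rooted` attribute from [strict_consensus()]); pass
#'   `assume_rooted = TRUE` for such trees from other sources.
#' @param bins number of ancestry classes for downstream colouring.
#' @param assume_rooted treat the basal node as a root even when the
#'   tree looks unrooted to [ape::is.rooted()].
#' @return a tibble of class `ancestry_map`: `label`, `depth`, `nd`,
#'   `bin`.
#' @export
node_distance <- function(tree, bins = 10, assume_rooted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree) && !isTRUE(attr(tree, "rooted")) &&
      !assume_rooted) {
    abort("node_distance needs a rooted tree")
  }
  ntip <- length(tree$tip.label)
  if (ntip < 2L) abort("need at least 2 leaves")
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- vapply(seq_len(ntip), function(tp) {
    d <- 0L
    v <- parent[tp]
    while (!is.na(v)) {
      d <- d + 1L
      v <- parent[v]
    }
    d
  }, integer(1))
  d_max <- max(depth)
  d_min <- min(depth)
  nd <- if (d_max == d_min) rep(0, ntip)
        else (depth - d_min) / (d_max - d_min)
  out <- tibble(
    label = tree$tip.label,
    depth = depth,
    nd = nd,
    bin = nd_bin(nd, bins)
  )
  structure(out, class = c("ancestry_map", class(out)), bins = bins)
}

nd_bin <- function(nd, bins) {
  pmin(bins, findInterval(nd, seq(0, 1, length.out = bins + 1L),
                          rightmost.closed = TRUE) )
}

#' Cumulative accretion curves along the nd timeline
#'
#' Orders the leaves by nd and accumulates counts per group, producing
#' the step function behind cumulative frequency plots of structural
#' (or molecular) accumulation over the relative timeline.
#'
#' @param amap an [node_distance()] result.
#' @param groups optional named vector mapping leaf label to group;
#'   default puts every leaf in one group.
#' @return a tibble `nd`, `group`, `count`, `cum_count`, `cum_frac`;
#'   within each group `cum_count` is nondecreasing and reaches the
#'   group size at `nd = 1`.
#' @export
cumulative_accretion <- function(amap, groups = NULL) {
  stopifnot(inherits(amap, "ancestry_map"))
  if (is.null(groups)) {
    groups <- setNames(rep("all", nrow(amap)), amap$label)
  }
  df <- tibble(
    label = amap$label, nd = amap$nd,
    group = unname(groups[amap$label])
  )
  if (anyNA(df$group)) {
    abort(sprintf("no group for leaf: %s",
                  paste(df$label[is.na(df$group)], collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$group, .data$nd)
  out <- df |>
    dplyr::count(.data$group, .data$nd, name = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      cum_count = cumsum(.data$count),
      cum_frac = .data$cum_count / sum(.data$count)
    ) |>
    dplyr::ungroup()
  structure(out, class = c("accretion_curve", class(out)))
}

#' Render an evolutionary heat map of ancestry
#'
#' Colours a secondary-structure layout by binned nd ancestry: ancient
#' substructures hot, recent ones cool.  Two template styles are
#' supported: a layout table (`label`, `x`, `y`, `shape` in
#' `rect`/`circle`) from which an SVG drawing is generated, or an
#' existing SVG document whose elements carry `id` attributes equal to
#' substructure labels, which is recoloured in place.  Template
#' elements without an nd value are painted grey and collected in a
#' warning.
#'
#' @param amap an [node_distance()] result.
#' @param template a data frame (`label`, `x`, `y`, `shape`), a path to
#'   such a TSV, or a path to / `xml_document` of an SVG template.
#' @param path optional output file for the SVG text.
#' @param bins number of colour classes over `[0, 1]`.
#' @param palette function(n) returning n colours, oldest first.
#' @return the SVG text (invisibly when written to `path`).
#' @export
render_heatmap <- function(amap, template, path = NULL, bins = 10,
                           palette = heat_palette) {
  stopifnot(inherits(amap, "ancestry_map"))
  cols <- palette(bins)
  fill_of <- function(labels) {
    hit <- match(labels, amap$label)
    out <- rep("#bbbbbb", length(labels))
    ok <- !is.na(hit)
    out[ok] <- cols[nd_bin(amap$nd[hit[ok]], bins)]
    if (any(!ok)) {
      warn(sprintf("no nd value for template element(s): %s (rendered grey)",
                   paste(labels[!ok], collapse = ", ")))
    }
    out
  }

  if (inherits(template, "xml_document") ||
      (is.character(template) && length(template) == 1 &&
       grepl("\\.svg$", template, ignore.case = TRUE))) {
    doc <- if (inherits(template, "xml_document")) template
           else xml2::read_xml(template)
    labs <- unique(amap$label)
    for (lb in labs) {
      nodes <- xml2::xml_find_all(doc, sprintf("//*[@id='%s']", lb))
      for (nd_el in nodes) {
        xml2::xml_set_attr(nd_el, "fill",
                           cols[nd_bin(amap$nd[amap$label == lb][1], bins)])
      }
    }
    txt <- as.character(doc)
  } else {
    layout <- if (is.character(template)) {
      utils::read.table(template, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else as.data.frame(template)
    need <- c("label", "x", "y", "shape")
    if (!all(need %in% names(layout))) {
      abort("layout template needs columns label, x, y, shape")
    }
    fills <- fill_of(layout$label)
    elements <- vapply(seq_len(nrow(layout)), function(k) {
      l <- layout[k, ]
      shp <- if (l$shape == "circle") {
        sprintf('<circle id="%s" cx="%g" cy="%g" r="9" fill="%s" stroke="black"/>',
                l$label, l$x, l$y, fills[k])
      } else {
        sprintf('<rect id="%s" x="%g" y="%g" width="24" height="12" fill="%s" stroke="black"/>',
                l$label, l$x - 12, l$y - 6, fills[k])
      }
      paste0(shp,
             sprintf('<text x="%g" y="%g" font-size="8" text-anchor="middle">%s</text>',
                     l$x, l$y + 3, l$label))
    }, character(1))
    width <- max(layout$x) + 60
    height <- max(layout$y) + 80
    breaks <- seq(0, 1, length.out = bins + 1L)
    legend <- vapply(seq_len(bins), function(b) {
      paste0(
        sprintf('<rect x="%g" y="%g" width="18" height="12" fill="%s" stroke="black"/>',
                10 + (b - 1) * 20, height - 40, cols[b]),
        sprintf('<text x="%g" y="%g" font-size="7" text-anchor="middle">%.1f</text>',
                10 + (b - 1) * 20, height - 14, breaks[b])
      )
    }, character(1))
    txt <- paste0(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%g" height="%g">',
              width, height),
      '<text x="10" y="16" font-size="10">ancestry (nd) heat map</text>',
      paste(elements, collapse = ""),
      paste(legend, collapse = ""),
      sprintf('<text x="%g" y="%g" font-size="8">nd</text>',
              10 + bins * 20 + 6, height - 30),
      "</svg>"
    )
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname render_heatmap
#' @param n number of colours.
#' @export
heat_palette <- function(n) {
  grDevices::colorRampPalette(
    c("#a50026", "#f46d43", "#fee090", "#74add1", "#313695")
  )(n)
}

#' @export
autoplot.ancestry_map <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$nd)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nd, y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$label),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$nd), size = 2) +
    ggplot2::scale_colour_gradientn(colours = heat_palette(10)) +
    ggplot2::labs(x = "node distance (nd, relative age)", y = NULL,
                  colour = "nd") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.accretion_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$nd, y = .data$cum_frac,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "node distance (nd, relative age)",
                  y = "cumulative frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.char_matrix <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"taxon", names_to = "character",
                        values_to = "symbol") |>
    dplyr::mutate(state = decode_state(.data$symbol))
  df$character <- factor(df$character, levels = object$chars$char_id)
  df$taxon <- factor(df$taxon, levels = rev(rownames(object$states)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$character, y = .data$taxon,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1,
                                                       size = 6))
}
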