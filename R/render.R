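# Deterministic SVG renderings of every pipeline result. SVG is built as
# plain text (no graphics device) so figures are diff-able and the tests can
# assert on content rather than pixels.

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_open <- function(w, h)
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                 'height="%d" viewBox="0 0 %d %d" font-family="sans-serif">'),
          round(w), round(h), round(w), round(h))

svg_line <- function(x1, y1, x2, y2, stroke = "black", width = 1,
                     dash = NULL)
  sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="%g"%s/>',
          x1, y1, x2, y2, stroke, width,
          if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash))

svg_text <- function(x, y, s, size = 11, anchor = "start", fill = "black")
  sprintf('<text x="%.1f" y="%.1f" font-size="%g" text-anchor="%s" fill="%s">%s</text>',
          x, y, size, anchor, fill, svg_esc(s))

svg_circle <- function(x, y, r, fill = "white", stroke = "black")
  sprintf('<circle cx="%.1f" cy="%.1f" r="%.1f" fill="%s" stroke="%s"/>',
          x, y, r, fill, stroke)

svg_rect <- function(x, y, w, h, fill = "steelblue", stroke = "none")
  sprintf('<rect x="%.1f" y="%.1f" width="%.2f" height="%.2f" fill="%s" stroke="%s"/>',
          x, y, w, h, fill, stroke)

svg_close <- function() "</svg>"

PALETTE <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
             "#e6ab02", "#a6761d", "#666666", "#1f78b4", "#b2df8a")

# layered layout of an rtree: tips at consecutive y slots (preorder order),
# internal y = mean of children, x = cumulative branch length from root
layout_rtree <- function(tree, x_scale = 3, y_step = 22) {
  kids <- rtree_children(tree)
  depth <- rtree_depths(tree)
  y <- numeric(rtree_n(tree))
  slot <- 0
  for (v in rtree_preorder(tree)) if (length(kids[[v]]) == 0) {
    slot <- slot + 1
    y[v] <- slot * y_step
  }
  for (v in rtree_postorder(tree)) if (length(kids[[v]]) > 0)
    y[v] <- mean(y[kids[[v]]])
  list(x = 30 + depth * x_scale, y = 20 + y, depth = depth)
}

#' Render the clone phylogeny with its non-zero clone-frequency table
#'
#' Tree on the left; one column per tumor sample on the right; one row per
#' clone tip. Cells whose frequency is zero are left blank so the
#' presence/absence pattern of clones across samples stands out.
#'
#' @param cp a `clone_phylogeny`
#' @param f clone frequency matrix (samples x clones)
#' @return a single SVG string
#' @export
render_clone_tree_with_frequencies <- function(cp, f) {
  tree <- cp$tree
  tips <- rtree_tips(tree)
  if (!all(colnames(f) %in% tree$label[tips]))
    stop("frequency matrix names missing clone(s): ",
         paste(setdiff(colnames(f), tree$label[tips]), collapse = ", "))
  maxd <- max(rtree_depths(tree))
  xs <- 260 / max(maxd, 1)
  lay <- layout_rtree(tree, x_scale = xs)
  col_w <- 70
  x_tab <- 30 + maxd * xs + 110
  w <- x_tab + col_w * nrow(f) + 20
  h <- 60 + 22 * (length(tips) + 1)
  out <- c(svg_open(w, h))
  for (v in seq_len(rtree_n(tree))) {
    p <- tree$parent[v]
    if (p == 0L) next
    out <- c(out, svg_line(lay$x[p], lay$y[p], lay$x[p], lay$y[v]),
             svg_line(lay$x[p], lay$y[v], lay$x[v], lay$y[v]))
  }
  for (s in seq_len(nrow(f)))
    out <- c(out, svg_text(x_tab + (s - 0.5) * col_w, 16, rownames(f)[s],
                           size = 10, anchor = "middle"))
  for (v in tips) {
    lab <- tree$label[v]
    out <- c(out, svg_text(lay$x[v] + 4, lay$y[v] + 4, lab))
    if (!lab %in% colnames(f)) next
    for (s in seq_len(nrow(f))) {
      val <- f[s, lab]
      if (val > 0)
        out <- c(out, svg_text(x_tab + (s - 0.5) * col_w, lay$y[v] + 4,
                               sprintf("%.2f", val), size = 10,
                               anchor = "middle"))
    }
  }
  paste(c(out, svg_close()), collapse = "\n")
}

# layout of the mutation tree (groups as circles, preorder slots)
layout_groups <- function(mtree, y_step = 70, x_step = 110) {
  g <- nrow(mtree$groups)
  depth_of <- integer(g)
  for (i in seq_len(g)) {
    d <- 1L; p <- mtree$group_parent[i]
    while (p > 0) { d <- d + 1L; p <- mtree$group_parent[p] }
    depth_of[i] <- d
  }
  kids <- lapply(seq_len(g), function(i) which(mtree$group_parent == i))
  y <- numeric(g)
  slot <- 0
  assign_y <- function(i) {
    if (length(kids[[i]]) == 0) {
      slot <<- slot + 1; y[i] <<- slot * y_step
    } else {
      for (k in kids[[i]]) assign_y(k)
      y[i] <<- mean(y[kids[[i]]])
    }
  }
  for (i in which(mtree$group_parent == 0)) assign_y(i)
  list(x = 60 + depth_of * x_step, y = 30 + y, depth = depth_of)
}

#' Render the mutational tree with driver-mutation timing
#'
#' Each mutation group is a circle showing the group id and its mutation
#' count; each driver mutation is a blue dot on the edge of the group that
#' contains it, labeled with the driver's display label; gene names are
#' listed in a legend block.
#'
#' @param mtree a `mutation_tree`
#' @return SVG string
#' @export
render_mutation_tree <- function(mtree) {
  lay <- layout_groups(mtree)
  g <- nrow(mtree$groups)
  w <- max(lay$x) + 180
  legend <- if (!is.null(mtree$drivers) && nrow(mtree$drivers) > 0)
    mtree$drivers else NULL
  h <- max(c(lay$y + 50, 120)) + (if (is.null(legend)) 0 else 0)
  out <- c(svg_open(w, h))
  x0 <- 30  # germline anchor
  y0 <- if (g > 0) mean(lay$y[mtree$group_parent == 0]) else 60
  for (i in seq_len(g)) {
    p <- mtree$group_parent[i]
    px <- if (p == 0) x0 else lay$x[p]
    py <- if (p == 0) y0 else lay$y[p]
    out <- c(out, svg_line(px, py, lay$x[i], lay$y[i], stroke = "#555"))
  }
  for (i in seq_len(g)) {
    out <- c(out,
             svg_circle(lay$x[i], lay$y[i], 18, fill = "#f2f2f2"),
             svg_text(lay$x[i], lay$y[i] - 2, mtree$groups$id[i], size = 10,
                      anchor = "middle"),
             svg_text(lay$x[i], lay$y[i] + 10, as.character(mtree$groups$count[i]),
                      size = 9, anchor = "middle"))
  }
  if (!is.null(legend)) {
    placed <- legend[!is.na(legend$group), , drop = FALSE]
    for (j in seq_len(nrow(placed))) {
      i <- match(placed$group[j], mtree$groups$id)
      p <- mtree$group_parent[i]
      px <- if (p == 0) x0 else lay$x[p]
      py <- if (p == 0) y0 else lay$y[p]
      t <- (j %% 3 + 1) / 4 + 0.25
      dx <- px + (lay$x[i] - px) * t
      dy <- py + (lay$y[i] - py) * t
      out <- c(out, svg_circle(dx, dy, 4, fill = "blue", stroke = "blue"),
               svg_text(dx + 6, dy + 3, placed$label[j], size = 9,
                        fill = "blue"))
    }
    out <- c(out, svg_text(10, 14, "Drivers:", size = 10))
    out <- c(out, svg_text(60, 14, paste(paste0(legend$label, "=", legend$gene),
                                         collapse = "  "), size = 10))
  }
  paste(c(out, svg_close()), collapse = "\n")
}

#' Render per-edge signature activity bars on the mutational tree
#'
#' One stacked horizontal bar per mutation group showing the fitted relative
#' activities of the retained signatures; a shared color legend maps
#' signatures to colors. Groups with no mutations are listed with a note.
#'
#' @param mtree a `mutation_tree`
#' @param bs a `branch_signatures` object
#' @return SVG string
#' @export
render_signature_layers <- function(mtree, bs) {
  sigs <- bs$signature_names
  cols <- stats::setNames(PALETTE[(seq_along(sigs) - 1) %% length(PALETTE) + 1],
                          sigs)
  g <- length(bs$groups)
  bar_w <- 160
  h <- 60 + 26 * g
  out <- c(svg_open(430, h))
  for (k in seq_along(sigs))
    out <- c(out, svg_rect(10 + (k - 1) * 90, 8, 10, 10, fill = cols[sigs[k]]),
             svg_text(24 + (k - 1) * 90, 17, sigs[k], size = 9))
  for (i in seq_len(g)) {
    y <- 30 + 26 * i
    out <- c(out, svg_text(10, y + 10, bs$groups[i], size = 10))
    f <- bs$fits[[i]]
    if (length(f$retained) == 0 || all(f$activities == 0)) {
      out <- c(out, svg_text(60, y + 10, "no mutations", size = 9,
                             fill = "#888"))
      next
    }
    x <- 60
    for (sg in f$retained) {
      wseg <- bar_w * as.numeric(f$activities[sg])
      if (wseg <= 0) next
      out <- c(out, svg_rect(x, y, wseg, 14, fill = cols[sg]))
      x <- x + wseg
    }
    note <- sprintf("cos=%.3f%s", f$fit_cosine,
                    if (nzchar(bs$flags[i])) paste0(" [", bs$flags[i], "]") else "")
    out <- c(out, svg_text(60 + bar_w + 8, y + 11, note, size = 9))
  }
  paste(c(out, svg_close()), collapse = "\n")
}

#' Render a 96-channel spectrum barplot for one branch
#'
#' Bars in canonical channel order, grouped by substitution class; channels
#' occupied by driver mutations on the branch are highlighted and labeled.
#'
#' @param spectrum named 96-vector of counts
#' @param title plot title (e.g. the group id)
#' @param driver_channels named character vector: channel label -> driver
#'   display label
#' @return SVG string
#' @export
render_spectrum <- function(spectrum, title = "", driver_channels = NULL) {
  canon <- sbs_channels()
  stopifnot(length(spectrum) == 96)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  class_col <- stats::setNames(
    c("#03bcee", "#010101", "#e32926", "#cac9c9", "#a1ce63", "#ebc6c4"),
    classes)
  w_bar <- 7
  out <- c(svg_open(96 * w_bar + 60, 180),
           svg_text(10, 16, title, size = 12))
  m <- max(spectrum, 1)
  for (i in seq_len(96)) {
    cl <- sub(".*\\[(.*)\\].*", "\\1", canon[i])
    x <- 30 + (i - 1) * w_bar
    hgt <- 120 * spectrum[i] / m
    out <- c(out, svg_rect(x, 150 - hgt, w_bar - 1.5, max(hgt, 0.1),
                           fill = class_col[cl]))
    if (!is.null(driver_channels) && canon[i] %in% names(driver_channels)) {
      out <- c(out, svg_circle(x + w_bar / 2, 150 - hgt - 8, 3,
                               fill = "blue", stroke = "blue"),
               svg_text(x + w_bar / 2, 150 - hgt - 14,
                        driver_channels[[canon[i]]], size = 8,
                        anchor = "middle", fill = "blue"))
    }
  }
  for (k in seq_along(classes))
    out <- c(out, svg_text(30 + (k - 1) * 16 * w_bar + 8 * w_bar, 168,
                           classes[k], size = 10, anchor = "middle"))
  paste(c(out, svg_close()), collapse = "\n")
}

#' Render the metastatic migration graph
#'
#' Sites on a circle, directed edges annotated with their supporting
#' mutation counts in parentheses; edges whose mutation count is zero are
#' drawn dashed and unannotated (a zero is not shown). The "Primary"
#' pseudo-node points at the inferred origin site(s).
#'
#' @param mg a `migration_graph`
#' @return SVG string
#' @export
render_migration_graph <- function(mg) {
  sites <- mg$sites
  n <- length(sites)
  cx <- 210; cy <- 170; R <- 120
  pos <- lapply(seq_len(max(n, 1)), function(i) {
    a <- 2 * pi * (i - 1) / max(n, 1)
    c(cx + R * cos(a), cy + R * sin(a))
  })
  names(pos) <- sites
  out <- c(svg_open(430, 340),
           '<defs><marker id="arr" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="auto"><path d="M0,0 L7,3 L0,6 z" fill="black"/></marker></defs>')
  out <- c(out, svg_circle(40, 30, 16, fill = "#ffe9a8"),
           svg_text(40, 34, "Primary", size = 9, anchor = "middle"))
  for (o in mg$origin) {
    p <- pos[[o]]
    out <- c(out, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black" marker-end="url(#arr)"/>',
      52, 40, p[1], p[2] - 18))
  }
  if (!is.null(mg$edges) && nrow(mg$edges) > 0) {
    for (k in seq_len(nrow(mg$edges))) {
      e <- mg$edges[k, ]
      a <- pos[[e$from]]; b <- pos[[e$to]]
      counts <- as.numeric(strsplit(e$counts, ",")[[1]])
      shown <- counts[counts > 0]
      dash <- if (all(counts == 0)) "4,3" else NULL
      out <- c(out, sprintf(
        '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"%s marker-end="url(#arr)"/>',
        a[1], a[2], (a[1] + 4 * b[1]) / 5, (a[2] + 4 * b[2]) / 5,
        if (is.null(dash)) "" else ' stroke-dasharray="4,3"'))
      if (length(shown))
        out <- c(out, svg_text((a[1] + b[1]) / 2, (a[2] + b[2]) / 2 - 4,
                               paste0("(", paste(shown, collapse = ","), ")"),
                               size = 10, anchor = "middle"))
    }
  }
  for (s in sites) {
    p <- pos[[s]]
    out <- c(out, svg_circle(p[1], p[2], 17, fill = "#dce9f7"),
             svg_text(p[1], p[2] + 3, s, size = 9, anchor = "middle"))
  }
  paste(c(out, svg_close()), collapse = "\n")
}

#' Render the sample tree (unrooted NJ layout)
#'
#' Simple equal-angle layout of the unrooted neighbor-joining tree with
#' sample labels at the tips.
#'
#' @param phy an [ape::phylo] tree
#' @return SVG string
#' @export
render_sample_tree <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  kids <- vector("list", n)
  parent <- integer(n)
  for (k in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[k, 1]]] <- c(kids[[phy$edge[k, 1]]], phy$edge[k, 2])
    parent[phy$edge[k, 2]] <- phy$edge[k, 1]
  }
  root <- ntip + 1L
  ntips_below <- function(v) {
    if (v <= ntip) return(1L)
    sum(vapply(kids[[v]], ntips_below, 0L))
  }
  elen <- stats::setNames(phy$edge.length, phy$edge[, 2])
  xs <- numeric(n); ys <- numeric(n)
  place <- function(v, x, y, a0, a1) {
    xs[v] <<- x; ys[v] <<- y
    a <- a0
    for (c in kids[[v]]) {
      frac <- ntips_below(c) / max(ntips_below(v), 1)
      am <- a + (a1 - a0) * frac / 2
      l <- 12 + 40 * elen[[as.character(c)]] / max(max(phy$edge.length), 1e-9)
      place(c, x + l * cos(am), y + l * sin(am), a, a + (a1 - a0) * frac)
      a <- a + (a1 - a0) * frac
    }
  }
  place(root, 250, 200, 0, 2 * pi)
  # normalize into the canvas
  xs <- xs - min(xs) + 30; ys <- ys - min(ys) + 30
  out <- c(svg_open(max(xs) + 120, max(ys) + 40))
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    out <- c(out, svg_line(xs[a], ys[a], xs[b], ys[b]))
  }
  for (t in seq_len(ntip))
    out <- c(out, svg_text(xs[t] + 4, ys[t] + 4, phy$tip.label[t], size = 10))
  paste(c(out, svg_close()), collapse = "\n")
}
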