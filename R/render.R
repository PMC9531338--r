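# Static SVG rendering of alignments and rare k-mer match profiles.
# Three modes: pair (two ids), one_vs_all (one focal id), global (paged).
# Geometry: horizontal sequence tracks; one grey quadrilateral per kept
# alignment spanning the two tracks (edges cross for minus-strand records);
# one red segment per k-mer match. Canvas width 1200 units, 80 units per
# lane, linear bp scaling; output is deterministic (no timestamps).

.SVG_PAD <- 60
.BAR_H <- 14
.TOP_MARGIN <- 30

#' Rendering options
#'
#' @param mode One of `"pair"`, `"one_vs_all"`, `"global"`.
#' @param show_kmers Draw red k-mer match segments?
#' @param min_mapq,min_kmapq Filter thresholds applied before drawing.
#' @param region Optional zoom window `list(seq_id=, start=, end=)`
#'   (pair/one_vs_all modes only).
#' @param per_page Alignments per page in global mode.
#' @param width Canvas width in SVG units.
#' @param lane_height Vertical spacing per lane in SVG units.
#' @return An object of class `render_options`.
#' @export
render_options <- function(mode = c("pair", "one_vs_all", "global"),
                           show_kmers = TRUE, min_mapq = 0L, min_kmapq = 0L,
                           region = NULL, per_page = 20L,
                           width = 1200, lane_height = 80) {
  mode <- match.arg(mode)
  per_page <- as.integer(per_page)
  if (per_page < 1L) stop("per_page must be >= 1")
  if (!is.null(region)) {
    if (mode == "global") stop("region zoom is only valid in pair/one_vs_all modes")
    stopifnot(!is.null(region$seq_id), !is.null(region$start), !is.null(region$end))
  }
  structure(list(mode = mode, show_kmers = isTRUE(show_kmers),
                 min_mapq = min_mapq, min_kmapq = min_kmapq, region = region,
                 per_page = per_page, width = width, lane_height = lane_height),
            class = "render_options")
}

.new_scene <- function(tracks, polys, segs, options) {
  structure(list(tracks = tracks, polys = polys, segs = segs,
                 width = options$width, lane_height = options$lane_height),
            class = "rkm_scene")
}

.empty_polys <- function() {
  data.frame(top = integer(0), bot = integer(0), q1 = numeric(0),
             q2 = numeric(0), t1 = numeric(0), t2 = numeric(0),
             strand = character(0))
}

.empty_segs <- function() {
  data.frame(top = integer(0), bot = integer(0), qx = numeric(0),
             tx = numeric(0))
}

# collect id -> length over all scored records (query and target roles)
.scored_seq_lengths <- function(scored) {
  out <- integer(0)
  for (s in scored) {
    out[s$aln$qname] <- s$aln$qlen
    out[s$aln$tname] <- s$aln$tlen
  }
  out
}

#' Zoom a scene to a region of one of its tracks
#'
#' Rescales the named track to `[start, end)`, clips polygon corners on that
#' track to the region, and drops polygons and match segments lying wholly
#' outside it. Other tracks are unaffected.
#'
#' @param scene A scene as built by the render functions.
#' @param region `list(seq_id=, start=, end=)`.
#' @return The zoomed scene.
#' @export
apply_zoom <- function(scene, region) {
  tr <- which(scene$tracks$id == region$seq_id)
  if (!length(tr)) stop("region sequence id not drawn: ", region$seq_id)
  start <- max(0, region$start)
  end <- min(scene$tracks$length[tr[1L]], region$end)
  if (end <= start) {
    warning("zoom region does not intersect ", region$seq_id, "; empty scene")
    scene$polys <- .empty_polys()
    scene$segs <- .empty_segs()
    scene$tracks$dom_start[tr] <- region$start
    scene$tracks$dom_end[tr] <- region$end
    return(scene)
  }
  scene$tracks$dom_start[tr] <- start
  scene$tracks$dom_end[tr] <- end
  p <- scene$polys
  if (nrow(p)) {
    keep <- rep(TRUE, nrow(p))
    for (i in seq_len(nrow(p))) {
      if (p$top[i] %in% tr) {
        lo <- min(p$q1[i], p$q2[i]); hi <- max(p$q1[i], p$q2[i])
        if (hi <= start || lo >= end) keep[i] <- FALSE
        p$q1[i] <- min(max(p$q1[i], start), end)
        p$q2[i] <- min(max(p$q2[i], start), end)
      }
      if (p$bot[i] %in% tr) {
        lo <- min(p$t1[i], p$t2[i]); hi <- max(p$t1[i], p$t2[i])
        if (hi <= start || lo >= end) keep[i] <- FALSE
        p$t1[i] <- min(max(p$t1[i], start), end)
        p$t2[i] <- min(max(p$t2[i], start), end)
      }
    }
    scene$polys <- p[keep, , drop = FALSE]
  }
  s <- scene$segs
  if (nrow(s)) {
    keep <- rep(TRUE, nrow(s))
    keep[s$top %in% tr & (s$qx < start | s$qx >= end)] <- FALSE
    keep[s$bot %in% tr & (s$tx < start | s$tx >= end)] <- FALSE
    scene$segs <- s[keep, , drop = FALSE]
  }
  scene
}

.fmt <- function(x) sprintf("%.2f", x)

# serialize a scene to an SVG 1.1 document (single string, deterministic)
.scene_to_svg <- function(scene) {
  tracks <- scene$tracks
  nlanes <- if (nrow(tracks)) max(tracks$lane) else 1L
  height <- .TOP_MARGIN + nlanes * scene$lane_height + 20
  xmap <- function(trk, bp) {
    d0 <- tracks$dom_start[trk]; d1 <- tracks$dom_end[trk]
    span <- max(d1 - d0, 1e-9)
    .SVG_PAD + (bp - d0) / span * (scene$width - 2 * .SVG_PAD)
  }
  ytop <- function(trk) .TOP_MARGIN + (tracks$lane[trk] - 1L) * scene$lane_height
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            .fmt(scene$width), .fmt(height), .fmt(scene$width), .fmt(height)))
  p <- scene$polys
  for (i in seq_len(nrow(p))) {
    yt <- ytop(p$top[i]) + .BAR_H
    yb <- ytop(p$bot[i])
    x1 <- xmap(p$top[i], p$q1[i]); x2 <- xmap(p$top[i], p$q2[i])
    x3 <- xmap(p$bot[i], p$t1[i]); x4 <- xmap(p$bot[i], p$t2[i])
    # '+': top-left joins bottom-left (q1->t1); '-': q1 joins t2, edges cross
    pts <- if (p$strand[i] == "+") {
      c(x1, yt, x2, yt, x4, yb, x3, yb)
    } else {
      c(x1, yt, x2, yt, x3, yb, x4, yb)
    }
    out <- c(out, sprintf(
      '<polygon class="aln" points="%s" fill="#bdbdbd" fill-opacity="0.65" stroke="#8c8c8c" stroke-width="0.5"/>',
      paste(.fmt(pts[c(1, 3, 5, 7)]), .fmt(pts[c(2, 4, 6, 8)]),
            sep = ",", collapse = " ")))
  }
  s <- scene$segs
  for (i in seq_len(nrow(s))) {
    out <- c(out, sprintf(
      '<line class="kmatch" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#d62728" stroke-width="0.8"/>',
      .fmt(xmap(s$top[i], s$qx[i])), .fmt(ytop(s$top[i]) + .BAR_H),
      .fmt(xmap(s$bot[i], s$tx[i])), .fmt(ytop(s$bot[i]))))
  }
  for (i in seq_len(nrow(tracks))) {
    y <- ytop(i)
    out <- c(out, sprintf(
      '<rect class="seqbar" x="%s" y="%s" width="%s" height="%s" fill="#4c78a8"/>',
      .fmt(.SVG_PAD), .fmt(y), .fmt(scene$width - 2 * .SVG_PAD), .fmt(.BAR_H)),
      sprintf('<text x="%s" y="%s" font-size="11" font-family="monospace">%s</text>',
              .fmt(.SVG_PAD), .fmt(y - 4), tracks$label[i]))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

.kept_for_render <- function(scored, options) {
  filter_alignments(scored, options$min_mapq, options$min_kmapq)$kept
}

.poly_row <- function(s, top, bot, focal_is_query = TRUE) {
  a <- s$aln
  if (focal_is_query) {
    data.frame(top = top, bot = bot, q1 = a$qstart, q2 = a$qend,
               t1 = a$tstart, t2 = a$tend, strand = a$strand)
  } else {
    data.frame(top = top, bot = bot, q1 = a$tstart, q2 = a$tend,
               t1 = a$qstart, t2 = a$qend, strand = a$strand)
  }
}

.seg_rows <- function(s, top, bot, focal_is_query = TRUE) {
  if (!nrow(s$matches)) return(.empty_segs())
  if (focal_is_query) {
    data.frame(top = top, bot = bot, qx = s$matches$qpos, tx = s$matches$tpos)
  } else {
    data.frame(top = top, bot = bot, qx = s$matches$tpos, tx = s$matches$qpos)
  }
}

#' Render the alignments between two sequences (pair mode)
#'
#' One grey polygon per alignment of `qname` (query) to `tname` (target)
#' passing the MAPQ/KMAPQ filters; with `show_kmers`, one red segment per
#' rare k-mer match. Output bytes are deterministic for fixed input.
#'
#' @param scored A `scored_alignments` list.
#' @param qname,tname Sequence ids (query and target).
#' @param options A [render_options()] object.
#' @param file Optional path; when given the SVG is written there.
#' @return The SVG document as a single string, invisibly.
#' @export
render_pair <- function(scored, qname, tname,
                        options = render_options("pair"), file = NULL) {
  lens <- .scored_seq_lengths(scored)
  if (!(qname %in% names(lens))) stop("unknown sequence id: ", qname)
  if (!(tname %in% names(lens))) stop("unknown sequence id: ", tname)
  kept <- .kept_for_render(scored, options)
  sel <- Filter(function(s) s$aln$qname == qname && s$aln$tname == tname, kept)
  tracks <- data.frame(id = c(qname, tname),
                       label = c(paste0(qname, " (query)"),
                                 paste0(tname, " (target)")),
                       lane = c(1L, 2L),
                       length = as.numeric(lens[c(qname, tname)]),
                       dom_start = c(0, 0),
                       dom_end = as.numeric(lens[c(qname, tname)]),
                       stringsAsFactors = FALSE)
  polys <- do.call(rbind, c(list(.empty_polys()),
                            lapply(sel, .poly_row, top = 1L, bot = 2L)))
  segs <- if (options$show_kmers) {
    do.call(rbind, c(list(.empty_segs()),
                     lapply(sel, .seg_rows, top = 1L, bot = 2L)))
  } else .empty_segs()
  scene <- .new_scene(tracks, polys, segs, options)
  if (!is.null(options$region)) scene <- apply_zoom(scene, options$region)
  svg <- .scene_to_svg(scene)
  if (!is.null(file)) writeLines(svg, file)
  invisible(svg)
}

#' Render every alignment involving one sequence (one-vs-all mode)
#'
#' The focal sequence is drawn once on the top lane; each partner (and each
#' role, if a partner appears both as query and as target of the focal id)
#' gets its own lane below, labeled with the partner's role.
#'
#' @param scored A `scored_alignments` list.
#' @param seq_id The focal sequence id.
#' @inheritParams render_pair
#' @return The SVG document as a single string, invisibly.
#' @export
render_one_vs_all <- function(scored, seq_id,
                              options = render_options("one_vs_all"),
                              file = NULL) {
  lens <- .scored_seq_lengths(scored)
  if (!(seq_id %in% names(lens))) stop("unknown sequence id: ", seq_id)
  kept <- .kept_for_render(scored, options)
  sel <- Filter(function(s) s$aln$qname == seq_id || s$aln$tname == seq_id,
                kept)
  # lane per (partner, partner role), in order of first appearance
  keys <- vapply(sel, function(s) {
    if (s$aln$qname == seq_id) paste0(s$aln$tname, "\rtarget")
    else paste0(s$aln$qname, "\rquery")
  }, "")
  ukeys <- unique(keys)
  pid <- sub("\r.*$", "", ukeys)
  prole <- sub("^.*\r", "", ukeys)
  tracks <- data.frame(
    id = c(seq_id, pid),
    label = c(seq_id, sprintf("%s (as %s)", pid, prole)),
    lane = seq_len(1L + length(ukeys)),
    length = as.numeric(lens[c(seq_id, pid)]),
    dom_start = 0,
    dom_end = as.numeric(lens[c(seq_id, pid)]),
    stringsAsFactors = FALSE)
  polys <- .empty_polys(); segs <- .empty_segs()
  for (j in seq_along(sel)) {
    s <- sel[[j]]
    lane <- 1L + match(keys[j], ukeys)
    fq <- s$aln$qname == seq_id  # focal drawn on top in its own role
    polys <- rbind(polys, .poly_row(s, top = 1L, bot = lane,
                                    focal_is_query = fq))
    if (options$show_kmers) {
      segs <- rbind(segs, .seg_rows(s, top = 1L, bot = lane,
                                    focal_is_query = fq))
    }
  }
  scene <- .new_scene(tracks, polys, segs, options)
  if (!is.null(options$region)) scene <- apply_zoom(scene, options$region)
  svg <- .scene_to_svg(scene)
  if (!is.null(file)) writeLines(svg, file)
  invisible(svg)
}

#' Render all alignments in pages (global mode)
#'
#' Kept alignments are ordered by (target name, target start) and grouped
#' `per_page` panels per document; each panel is a two-track query/target
#' pair.
#'
#' @param scored A `scored_alignments` list.
#' @inheritParams render_pair
#' @param file_prefix Optional path prefix; pages are written to
#'   `<prefix>_page001.svg`, `<prefix>_page002.svg`, ...
#' @return List of SVG document strings, one per page, invisibly.
#' @export
render_global <- function(scored, options = render_options("global"),
                          file_prefix = NULL) {
  kept <- .kept_for_render(scored, options)
  if (!length(kept)) {
    warning("no alignments pass the filters; nothing to draw")
    return(invisible(list()))
  }
  ord <- order(vapply(kept, function(s) s$aln$tname, ""),
               vapply(kept, function(s) s$aln$tstart, 0L))
  kept <- kept[ord]
  pages <- split(kept, ceiling(seq_along(kept) / options$per_page))
  svgs <- vector("list", length(pages))
  for (pg in seq_along(pages)) {
    chunk <- pages[[pg]]
    tracks <- do.call(rbind, lapply(seq_along(chunk), function(j) {
      a <- chunk[[j]]$aln
      data.frame(id = c(a$qname, a$tname),
                 label = c(paste0(a$qname, " (query)"),
                           paste0(a$tname, " (target)")),
                 lane = c(2L * j - 1L, 2L * j),
                 length = as.numeric(c(a$qlen, a$tlen)),
                 dom_start = 0,
                 dom_end = as.numeric(c(a$qlen, a$tlen)),
                 stringsAsFactors = FALSE)
    }))
    polys <- .empty_polys(); segs <- .empty_segs()
    for (j in seq_along(chunk)) {
      s <- chunk[[j]]
      polys <- rbind(polys, .poly_row(s, top = 2L * j - 1L, bot = 2L * j))
      if (options$show_kmers) {
        segs <- rbind(segs, .seg_rows(s, top = 2L * j - 1L, bot = 2L * j))
      }
    }
    svgs[[pg]] <- .scene_to_svg(.new_scene(tracks, polys, segs, options))
    if (!is.null(file_prefix)) {
      writeLines(svgs[[pg]], sprintf("%s_page%03d.svg", file_prefix, pg))
    }
  }
  invisible(svgs)
}
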