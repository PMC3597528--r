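#' Passive space constant of a cylindrical cable
#'
#' @param diameter cable diameter (um)
#' @param Rm specific membrane resistance (ohm cm^2)
#' @param Ri axial resistivity (ohm cm)
#' @return space constant lambda in um
#' @export
space_constant <- function(diameter, Rm = 28000, Ri = 200) {
  sqrt((diameter * 1e-4) * Rm / (4 * Ri)) * 1e4
}

#' Map path distances to dendritic regions
#'
#' Distances at or below the proximal boundary are "proximal", distances
#' strictly beyond the distal boundary are "distal", everything between is
#' "dendrite" (the middle region). The soma is labelled separately by the
#' morphology builders.
#'
#' @param path_distance path distance from the soma (um)
#' @param boundaries numeric of length 2: c(proximal_max, distal_min) in um
#' @return character vector of region labels
#' @export
region_of <- function(path_distance, boundaries = c(50, 100)) {
  stopifnot(length(boundaries) == 2, boundaries[1] <= boundaries[2])
  ifelse(path_distance <= boundaries[1], "proximal",
         ifelse(path_distance > boundaries[2], "distal", "dendrite"))
}

new_morphology <- function(compartments, region_boundaries, coords = NULL) {
  structure(list(compartments = compartments,
                 region_boundaries = region_boundaries,
                 coords = coords),
            class = "rgc_morphology")
}

soma_row <- function(soma_diameter) {
  data.frame(id = 1L, parent_id = NA_integer_, path_distance = 0,
             x_start = 0, length = 0, diameter = soma_diameter,
             region = "soma", area = pi * (soma_diameter * 1e-4)^2,
             stringsAsFactors = FALSE)
}

#' Build a soma plus unbranched dendrite morphology
#'
#' The dendrite is divided into compartments whose electrotonic length
#' (physical length over the local space constant) does not exceed
#' \code{max_electrotonic_step}. The soma is a single isopotential
#' spherical compartment.
#'
#' @param dendrite_length dendrite length (um); 0 gives a soma-only cell
#' @param diameter dendrite diameter (um); a scalar for a uniform cable or
#'   a length-2 vector c(base, tip) for a linear taper
#' @param region_boundaries c(proximal_max, distal_min) in um
#' @param max_electrotonic_step maximum compartment length as a fraction of
#'   the local space constant
#' @param Rm,Ri passive properties used for the space constant
#' @param soma_diameter soma diameter (um)
#' @return an object of class \code{rgc_morphology}
#' @export
build_unbranched_cable <- function(dendrite_length, diameter = 0.6,
                                   region_boundaries = c(50, 100),
                                   max_electrotonic_step = 0.1,
                                   Rm = 28000, Ri = 200,
                                   soma_diameter = 20) {
  stopifnot(dendrite_length >= 0, max_electrotonic_step > 0)
  if (any(diameter <= 0)) {
    stop("non-positive dendrite diameter (", paste(diameter, collapse = ", "),
         " um) in cable specification")
  }
  if (soma_diameter <= 0) stop("non-positive soma diameter")
  comps <- soma_row(soma_diameter)
  if (dendrite_length > 0) {
    diam_at <- if (length(diameter) == 1) {
      function(x) rep(diameter, length(x))
    } else {
      function(x) diameter[1] + (diameter[2] - diameter[1]) * x / dendrite_length
    }
    # adaptive walk: each compartment spans at most max_step * local lambda
    edges <- 0
    x <- 0
    while (x < dendrite_length - 1e-9) {
      lam <- space_constant(diam_at(x), Rm, Ri)
      dx <- min(max_electrotonic_step * lam, dendrite_length - x)
      x <- x + dx
      edges <- c(edges, x)
    }
    x0 <- edges[-length(edges)]
    x1 <- edges[-1]
    mid <- (x0 + x1) / 2
    d <- diam_at(mid)
    len <- x1 - x0
    n <- length(mid)
    comps <- rbind(comps, data.frame(
      id = seq_len(n) + 1L,
      parent_id = seq_len(n),
      path_distance = mid,
      x_start = x0,
      length = len,
      diameter = d,
      region = region_of(mid, region_boundaries),
      area = pi * d * 1e-4 * len * 1e-4,
      stringsAsFactors = FALSE))
  }
  rownames(comps) <- NULL
  new_morphology(comps, region_boundaries)
}

#' Total dendritic path length of a morphology
#' @param morphology an \code{rgc_morphology}
#' @return total cable length (um), excluding the soma
#' @export
total_dendrite_length <- function(morphology) {
  sum(morphology$compartments$length)
}

#' @export
print.rgc_morphology <- function(x, ...) {
  cc <- x$compartments
  cat("rgc_morphology:", nrow(cc), "compartments,",
      round(total_dendrite_length(x), 1), "um of dendrite\n")
  cat("  regions:", paste(names(table(cc$region)), table(cc$region),
                          sep = "=", collapse = ", "), "\n")
  cat("  boundaries: proximal <=", x$region_boundaries[1],
      "um, distal >", x$region_boundaries[2], "um\n")
  invisible(x)
}

#' Load a morphology from SWC text
#'
#' Reads standard 7-column SWC (id, type, x, y, z, radius, parent; parent
#' -1 marks the root). Path distances are accumulated 3-D inter-node
#' distances; each inter-node segment becomes one or more compartments so
#' that the electrotonic-step criterion holds.
#'
#' @param swc SWC file path or a character vector of SWC lines
#' @param region_boundaries,max_electrotonic_step,Rm,Ri as in
#'   \code{\link{build_unbranched_cable}}
#' @return an \code{rgc_morphology}
#' @export
load_swc <- function(swc, region_boundaries = c(50, 100),
                     max_electrotonic_step = 0.1, Rm = 28000, Ri = 200) {
  lines <- if (length(swc) == 1 && !grepl("\n", swc) && file.exists(swc)) {
    readLines(swc)
  } else {
    unlist(strsplit(swc, "\n"))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- lines[keep]
  if (length(rows) == 0) stop("SWC input contains no data rows")
  fields <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(fields, length, 0L) != 7)
  if (length(bad)) {
    stop("malformed SWC (expected 7 columns) at line ", lineno[bad[1]])
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5],
                   radius = m[, 6], parent = as.integer(m[, 7]))
  if (any(df$radius < 0)) {
    stop("negative radius in SWC at line ", lineno[which(df$radius < 0)[1]])
  }
  root <- which(df$parent == -1)
  if (length(root) == 0) stop("SWC has no root node (parent = -1)")
  if (length(root) > 1) stop("SWC has multiple root nodes")
  idx <- match(df$parent, df$id)
  seen <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] != -1) {
      if (is.na(idx[i]) || !seen[idx[i]]) {
        stop("SWC parent does not precede child (cycle or missing parent) ",
             "at line ", lineno[i])
      }
    }
    seen[i] <- TRUE
  }
  # path distance of every node from the root
  pd <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] == -1) { pd[i] <- 0; next }
    p <- idx[i]
    step <- sqrt((df$x[i] - df$x[p])^2 + (df$y[i] - df$y[p])^2 +
                 (df$z[i] - df$z[p])^2)
    pd[i] <- pd[p] + step
  }
  soma_d <- 2 * df$radius[root]
  comps <- soma_row(soma_d)
  coords <- data.frame(id = 1L, x = df$x[root], y = df$y[root], z = df$z[root])
  # map: swc node index -> compartment id of the compartment ending there
  node_comp <- integer(nrow(df))
  node_comp[root] <- 1L
  next_id <- 2L
  ord <- order(df$id)
  for (i in ord) {
    if (df$parent[i] == -1) next
    p <- idx[i]
    seg_len <- pd[i] - pd[p]
    if (seg_len <= 0) { node_comp[i] <- node_comp[p]; next }
    d <- df$radius[i] + df$radius[p]       # mean of the two node diameters
    if (d <= 0) stop("zero diameter segment in SWC at line ", lineno[i])
    lam <- space_constant(d, Rm, Ri)
    nseg <- max(1L, ceiling(seg_len / (max_electrotonic_step * lam)))
    sub_len <- seg_len / nseg
    par_comp <- node_comp[p]
    for (k in seq_len(nseg)) {
      x0 <- pd[p] + (k - 1) * sub_len
      mid <- x0 + sub_len / 2
      comps <- rbind(comps, data.frame(
        id = next_id, parent_id = par_comp, path_distance = mid,
        x_start = x0, length = sub_len, diameter = d,
        region = region_of(mid, region_boundaries),
        area = pi * d * 1e-4 * sub_len * 1e-4,
        stringsAsFactors = FALSE))
      par_comp <- next_id
      next_id <- next_id + 1L
    }
    node_comp[i] <- par_comp
    coords <- rbind(coords, data.frame(id = par_comp, x = df$x[i],
                                       y = df$y[i], z = df$z[i]))
  }
  rownames(comps) <- NULL
  new_morphology(comps, region_boundaries, coords = coords)
}

#' Write a morphology as SWC text
#'
#' Inverse of \code{\link{load_swc}} up to compartment subdivision: one SWC
#' node is written per compartment end. Morphologies built in-package have
#' no 3-D coordinates, so branches are laid out along the x axis at their
#' path distance, which preserves all path distances exactly.
#'
#' @param morphology an \code{rgc_morphology}
#' @param path optional output file; if missing the SWC lines are returned
#' @return character vector of SWC lines, invisibly when written to a file
#' @export
write_swc <- function(morphology, path = NULL) {
  cc <- morphology$compartments
  lines <- character(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    if (is.na(cc$parent_id[i])) {
      lines[i] <- sprintf("%d 1 0 0 0 %.6f -1", cc$id[i], cc$diameter[i] / 2)
    } else {
      xend <- cc$x_start[i] + cc$length[i]
      lines[i] <- sprintf("%d 3 %.6f 0 0 %.6f %d", cc$id[i], xend,
                          cc$diameter[i] / 2, cc$parent_id[i])
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Serialize a morphology to a tabular text file (one compartment per row)
#' @param morphology an \code{rgc_morphology}
#' @param path output file
#' @export
write_morphology_table <- function(morphology, path) {
  utils::write.table(morphology$compartments, path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a morphology from the tabular format
#' @param path file written by \code{\link{write_morphology_table}}
#' @param region_boundaries boundaries to attach
#' @return an \code{rgc_morphology}
#' @export
read_morphology_table <- function(path, region_boundaries = c(50, 100)) {
  cc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cc$parent_id <- suppressWarnings(as.integer(cc$parent_id))
  new_morphology(cc, region_boundaries)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Place synapses at statistically regular intervals along the dendrites
#'
#' Successive inter-synapse path intervals are drawn from a gamma
#' distribution with mean \code{mean_spacing} and mean/SD equal to
#' \code{regularity} (shape = regularity^2). At a branch point the residual
#' distance to the next synapse is carried into each daughter branch.
#'
#' @param morphology an \code{rgc_morphology}
#' @param mean_spacing mean inter-synapse interval (um)
#' @param regularity mean/SD of the interval distribution; large values
#'   approach perfectly regular spacing
#' @param seed RNG seed for reproducible placement (optional)
#' @return data.frame with columns compartment_id, offset (0-1 along the
#'   compartment) and path_distance, sorted by path distance
#' @export
place_synapses <- function(morphology, mean_spacing = 10, regularity = 8,
                           seed = NULL) {
  stopifnot(mean_spacing > 0, regularity > 0)
  cc <- morphology$compartments
  shape <- regularity^2
  scale <- mean_spacing / shape
  children <- split(cc$id[-1], cc$parent_id[-1])
  out <- list()
  with_seed(seed, {
    walk <- function(comp_id, residual) {
      row <- which(cc$id == comp_id)
      len <- cc$length[row]
      pos <- residual
      while (pos <= len) {
        out[[length(out) + 1]] <<- data.frame(
          compartment_id = comp_id,
          offset = if (len > 0) pos / len else 0,
          path_distance = cc$x_start[row] + pos)
        pos <- pos + stats::rgamma(1, shape = shape, scale = scale)
      }
      residual_next <- pos - len
      for (ch in children[[as.character(comp_id)]]) {
        walk(ch, residual_next)
      }
    }
    root <- cc$id[is.na(cc$parent_id)]
    first <- stats::rgamma(1, shape = shape, scale = scale)
    for (ch in children[[as.character(root)]]) walk(ch, first)
  })
  if (length(out) == 0) {
    return(data.frame(compartment_id = integer(), offset = numeric(),
                      path_distance = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$path_distance), ]
  rownames(res) <- NULL
  res
}
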