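#' Create a phantom specification
#'
#' The defaults describe the desk-scale study conditions used throughout the
#' package tests: a 128 x 128 x 280 um block imaged at 0.5 um/pixel in 48
#' sections of 7 um, three arteriole trees feeding sheathed capillaries with
#' one to four covered bifurcations, open-ended side branches, three bypass
#' capillaries, two capillary-venule contacts, B cells around every sheath,
#' and per-section rigid jitter plus Gaussian noise.
#'
#' @param domainSizeUm,pixelSizeUm,sectionThicknessUm acquisition geometry.
#' @param nArterioles,branchesPerArteriole,sheathBifurcationDepth,sideBranchesPerSheath
#'   vascular content controls (ranges are length-2 integer vectors).
#' @param nBypassCapillaries,nVenuleContacts,bcellDensity further content.
#' @param jitterTranslationPx,jitterRotationDeg per-section jitter amplitudes.
#' @param lostSectionIndices 0-based indices of lost sections.
#' @param noiseSd Gaussian noise sd in 8-bit units.
#' @param radiiUm named vessel radii in um.
#' @param stemLengthUm arteriole stem length; NA = 20 percent of the depth.
#' @param seed integer seed.
#' @return a validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(nArterioles = 1L, seed = 7L)
#' @export
phantomSpec <- function(domainSizeUm = c(128, 128, 336),
                        pixelSizeUm = 0.5,
                        sectionThicknessUm = 7,
                        nArterioles = 3L,
                        branchesPerArteriole = c(2L, 3L),
                        sheathBifurcationDepth = c(1L, 4L),
                        sideBranchesPerSheath = c(1L, 2L),
                        nBypassCapillaries = 3L,
                        nVenuleContacts = 2L,
                        bcellDensity = 4,
                        jitterTranslationPx = 5,
                        jitterRotationDeg = 1,
                        lostSectionIndices = integer(0),
                        noiseSd = 3,
                        radiiUm = c(stem = 7, branch = 4.5, sheathed = 3.5,
                                    side = 2, network = 3, bypass = 2.5,
                                    venule = 10, sheathInner = 4.5,
                                    sheathOuter = 10, bcell = 3.5),
                        stemLengthUm = NA_real_,
                        seed = 1L) {
  rng <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1) c(x, x) else x
  }
  new("PhantomSpec",
      domainSizeUm = domainSizeUm, pixelSizeUm = pixelSizeUm,
      sectionThicknessUm = sectionThicknessUm,
      nArterioles = as.integer(nArterioles),
      branchesPerArteriole = rng(branchesPerArteriole),
      sheathBifurcationDepth = rng(sheathBifurcationDepth),
      sideBranchesPerSheath = rng(sideBranchesPerSheath),
      nBypassCapillaries = as.integer(nBypassCapillaries),
      nVenuleContacts = as.integer(nVenuleContacts),
      bcellDensity = bcellDensity,
      jitterTranslationPx = jitterTranslationPx,
      jitterRotationDeg = jitterRotationDeg,
      lostSectionIndices = as.integer(lostSectionIndices),
      noiseSd = noiseSd, radiiUm = radiiUm,
      stemLengthUm = as.numeric(stemLengthUm), seed = as.integer(seed))
}

#' Build the vascular ground truth of a phantom
#'
#' Constructs a deterministic (seeded) centerline graph: arteriole stems and
#' branches (SMA+CD34), sheathed capillaries whose sheaths (CD271) cover the
#' sampled number of dichotomous bifurcations, open-ended side branches that
#' cross the sheath and end free at its surface, post-sheath network
#' capillaries, non-sheathed bypass capillaries, an optional venule with
#' capillary contacts, and B cells (CD20) around the sheaths.  The first
#' arteriole hosts a designed long sheathed path (the "hero" path) covering
#' the maximal sampled bifurcation depth, whose entry-to-exit centerline
#' length is recorded for geodesic validation.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomGroundTruth}.
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  with_seed(spec@seed, function() build_phantom_impl(spec))
}

build_phantom_impl <- function(spec) {
  L <- spec@domainSizeUm
  r <- spec@radiiUm
  margin <- max(r["sheathOuter"], r["venule"]) + 4

  nodes <- matrix(numeric(0), 0, 3)
  edges <- data.frame(from = integer(0), to = integer(0),
                      radiusUm = numeric(0), class = character(0),
                      sheath = integer(0), venuleContact = logical(0))
  sheaths <- list()
  bcells <- matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x", "y", "z", "r")))
  hero <- list()

  addNode <- function(p) {
    nodes <<- rbind(nodes, as.numeric(p))
    nrow(nodes)
  }
  addEdge <- function(from, to, radius, class, sheath = NA_integer_,
                      contact = FALSE) {
    edges[nrow(edges) + 1, ] <<- list(as.integer(from), as.integer(to),
                                      as.numeric(radius), class,
                                      as.integer(sheath), contact)
  }
  sampleRange <- function(rg) {
    if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)
  }
  clampXy <- function(p) {
    p[1] <- min(max(p[1], margin), L[1] - margin)
    p[2] <- min(max(p[2], margin), L[2] - margin)
    p
  }

  # clearance corridor around the designed long sheathed path: once it is
  # built, later vessels are pushed out of a tube around its centerline so
  # no touching structure (after grayscale closing) can short-circuit the
  # entry-to-exit geodesic
  heroPoly <- NULL
  heroClearUm <- 26
  pushOffHero <- function(p) {
    if (is.null(heroPoly)) return(p)
    best <- Inf; q <- NULL
    for (s in seq_len(nrow(heroPoly) - 1)) {
      a <- heroPoly[s, ]; b <- heroPoly[s + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-9)
      t <- min(max(t, 0), 1)
      cand <- a + t * ab
      d2 <- sum((p - cand)^2)
      if (d2 < best) { best <- d2; q <- cand }
    }
    d <- sqrt(best)
    if (d >= heroClearUm) return(p)
    dir <- p[1:2] - q[1:2]
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-6) dir <- c(1, 0) else dir <- dir / nd
    p[1:2] <- q[1:2] + dir * heroClearUm
    # soft domain clamp: escaping the corridor outranks the placement margin
    p[1] <- min(max(p[1], 4), L[1] - 4)
    p[2] <- min(max(p[2], 4), L[2] - 4)
    p
  }

  # grow one sheathed capillary: a wiggly main path with `depth` covered
  # bifurcations, child stubs crossing the shell, open-ended side branches,
  # the sheath record and its B cells; returns exit node + hero bookkeeping.
  # The hero variant is a long, gently turning helix (radius ~18 um, 45
  # degrees and 16 um of depth per segment): bends this mild survive the
  # grayscale closing unchanged, the in-plane speed stays close to the tube
  # diameter per section so the stain stays well above the iso-value, the
  # windings sit ~128 um apart in z, and the entry-to-exit surface geodesic
  # comfortably exceeds 300 um.
  growSheathedPath <- function(start, anchor, depth, hero, cellHalf) {
    r <- spec@radiiUm
    nseg <- if (hero) 16L else max(2L * depth, 3L)
    dz <- if (hero) 16 else 11
    lat <- if (hero) min(18.3, cellHalf - 3) else min(7, cellHalf - 2)

    pathIds <- start
    cur <- start
    phi0 <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(nseg)) {
      if (hero) {
        phi <- phi0 + s * pi / 4
        p <- c(anchor[1] + lat * cos(phi) + stats::runif(1, -0.5, 0.5),
               anchor[2] + lat * sin(phi) + stats::runif(1, -0.5, 0.5),
               nodes[cur, 3] + dz)
      } else {
        phi <- phi0 + s * 2.399963  # golden-angle turn keeps the path compact
        p <- nodes[cur, ] + c(lat * cos(phi), lat * sin(phi), dz)
      }
      for (j in 1:2) {
        if (abs(p[j] - anchor[j]) > cellHalf)
          p[j] <- anchor[j] + sign(p[j] - anchor[j]) * cellHalf
      }
      p <- clampXy(p)
      if (!hero) p <- pushOffHero(p)
      p[3] <- min(p[3], L[3] - 14)
      nxt <- addNode(p)
      pathIds <- c(pathIds, nxt)
      cur <- nxt
    }
    sheathId <- length(sheaths) + 1L
    mainEdges <- integer(0)
    for (s in seq_len(length(pathIds) - 1)) {
      addEdge(pathIds[s], pathIds[s + 1], r["sheathed"], "sheathed_capillary",
              sheath = sheathId)
      mainEdges <- c(mainEdges, nrow(edges))
    }

    # covered dichotomous bifurcations: child leaves the main path inside
    # the sheath, crosses the shell, ends shortly outside as cord capillary
    bifAt <- unique(round(seq(2, length(pathIds) - 1, length.out = depth)))
    for (bn in bifAt) {
      base <- nodes[pathIds[bn], ]
      dirxy <- base[1:2] - anchor
      nrm <- sqrt(sum(dirxy^2))
      dirxy <- if (nrm < 1) c(1, 0) else dirxy / nrm
      inPos <- clampXy(base + c(dirxy * (r["sheathOuter"] - 2), 4))
      if (!hero) inPos <- pushOffHero(inPos)
      inId <- addNode(inPos)
      addEdge(pathIds[bn], inId, r["sheathed"], "sheathed_capillary",
              sheath = sheathId)
      if (!hero) {
        # the child joins the cord network; the hero's children end free at
        # the shell so nothing can bridge onto the designed geodesic path
        outId <- addNode(pushOffHero(clampXy(nodes[inId, ] + c(dirxy * 10, 6))))
        addEdge(inId, outId, r["network"], "network_capillary")
      }
    }

    # open-ended side branches: short radial vessels ending free at the
    # sheath surface (degree-1 endpoints)
    nside <- if (spec@sideBranchesPerSheath[2] == 0) 0L else
      sampleRange(spec@sideBranchesPerSheath)
    if (nside > 0) {
      at <- unique(round(seq(1.6, length(pathIds) - 0.6, length.out = nside + 2)))
      at <- utils::head(setdiff(at, bifAt), nside)
      for (sn in at) {
        base <- nodes[pathIds[sn], ]
        phi <- stats::runif(1, 0, 2 * pi)
        tip <- clampXy(base + c(cos(phi), sin(phi), 0) * as.numeric(r["sheathOuter"]))
        if (!hero) tip <- pushOffHero(tip)
        tipId <- addNode(tip)
        addEdge(pathIds[sn], tipId, r["side"], "side_branch_open",
                sheath = sheathId)
      }
    }

    sheaths[[sheathId]] <<- list(
      edges = mainEdges, pathNodes = pathIds,
      innerRadiusUm = as.numeric(r["sheathInner"]),
      outerRadiusUm = as.numeric(r["sheathOuter"]),
      nBifurcations = depth,
      entry = pathIds[1], exit = pathIds[length(pathIds)])

    nb <- round(spec@bcellDensity)
    if (nb > 0) {
      for (k in seq_len(nb)) {
        seg <- sample(length(pathIds) - 1, 1)
        t <- stats::runif(1)
        c0 <- nodes[pathIds[seg], ] * (1 - t) + nodes[pathIds[seg + 1], ] * t
        phi <- stats::runif(1, 0, 2 * pi)
        rho <- stats::runif(1, r["sheathOuter"] - 2, r["sheathOuter"] + 3)
        pos <- c0 + c(rho * cos(phi), rho * sin(phi), stats::runif(1, -3, 3))
        pos <- pmin(pmax(pos, 2), L - 2)
        bcells <<- rbind(bcells, c(pos, r["bcell"]))
      }
    }

    heroInfo <- list()
    if (hero) {
      segs <- nodes[pathIds[-1], , drop = FALSE] -
        nodes[pathIds[-length(pathIds)], , drop = FALSE]
      heroInfo <- list(nodes = pathIds, entry = pathIds[1],
                       exit = pathIds[length(pathIds)],
                       sheathId = sheathId,
                       lengthUm = sum(sqrt(rowSums(segs^2))))
      heroPoly <<- nodes[pathIds, , drop = FALSE]
    }
    list(exit = pathIds[length(pathIds)], hero = heroInfo)
  }

  if (spec@nArterioles > 0) {
    # arteriole anchor positions on a jittered grid; the venule corner is
    # reserved when contacts are requested
    ncol_ <- ceiling(sqrt(spec@nArterioles))
    nrow_ <- ceiling(spec@nArterioles / ncol_)
    cw <- (L[1] - 2 * margin) / ncol_
    ch <- (L[2] - 2 * margin) / nrow_
    if (cw < 2 * r["sheathOuter"] || ch < 2 * r["sheathOuter"])
      stop("infeasible phantom: domain too small in x/y for n_arterioles ",
           "non-overlapping arteriole territories (violated: cell >= 2 x sheath outer radius)")
    anchors <- t(sapply(seq_len(spec@nArterioles) - 1L, function(i) {
      cx <- margin + (i %% ncol_ + 0.5) * cw
      cy <- margin + (i %/% ncol_ + 0.5) * ch
      c(cx, cy)
    }))

    stemLen <- if (is.na(spec@stemLengthUm)) 0.1 * L[3] else spec@stemLengthUm
    if (stemLen + 12 > L[3])
      stop("infeasible phantom: stem length exceeds domain depth (violated: stem + margins <= z extent)")

    # terminal arteries: near-vertical columns spanning the whole depth, the
    # large persistent structures real ROIs contain; arteriole stems branch
    # off them, and the registration relies on such slowly moving landmarks
    arteryTops <- integer(0)
    withArteries <- spec@nArterioles > 1 || spec@branchesPerArteriole[2] > 0
    if (withArteries) {
      # kept clear of the first cell, which hosts the designed long path
      artXy <- rbind(c(margin + 2, L[2] * 0.84),
                     c(L[1] - margin - 2, L[2] * 0.35),
                     c(L[1] * 0.84, margin + 2),
                     c(L[1] * 0.4, L[2] - margin - 2),
                     c(L[1] * 0.69, L[2] * 0.69),
                     c(L[1] * 0.655, margin + 4),
                     c(margin + 4, L[2] * 0.655))
      for (ai in seq_len(nrow(artXy))) {
        prev <- addNode(c(artXy[ai, ], 4))
        arteryTops <- c(arteryTops, prev)
        z <- 4
        while (z < L[3] - 6) {
          z <- z + 20
          p <- c(artXy[ai, ] + runif(2, -0.2, 0.2), min(z, L[3] - 4))
          nxt <- addNode(p)
          addEdge(prev, nxt, r["stem"], "arteriole_stem")
          prev <- nxt
        }
      }
    }

    networkNodes <- list()  # per arteriole: node ids available for linking

    for (a in seq_len(spec@nArterioles)) {
      isHero <- a == 1L
      top <- addNode(c(anchors[a, ], 6))
      stemEnd <- addNode(c(anchors[a, ], 6 + stemLen))
      addEdge(top, stemEnd, r["stem"], "arteriole_stem")
      if (length(arteryTops) > 0) {
        d2a <- colSums((t(nodes[arteryTops, 1:2, drop = FALSE]) - anchors[a, ])^2)
        addEdge(arteryTops[which.min(d2a)], top, r["branch"], "arteriole_stem")
      }

      nb <- sampleRange(spec@branchesPerArteriole)
      if (nb == 0) next
      netIds <- integer(0)

      # non-sheathed cord capillaries leaving the arteriole end: they keep
      # the red pulp network realistically dense through the whole depth and
      # give the registration stable, slowly drifting cross-sections.  The
      # hero tree gets none - its territory is reserved for the designed
      # long sheathed path, which must stay free of touching bypass routes
      for (cp in seq_len(if (isHero) 0 else 7)) {
        phi <- 2 * pi * cp / 6
        first <- addNode(clampXy(nodes[stemEnd, ] +
                                   c(runif(1, 8, 16) * cos(phi),
                                     runif(1, 8, 16) * sin(phi),
                                     runif(1, 6, 10))))
        addEdge(stemEnd, first, r["network"], "network_capillary")
        cur <- first
        nseg <- 0
        while (nodes[cur, 3] < L[3] - 10 && nseg < 24) {
          p <- pushOffHero(clampXy(nodes[cur, ] + c(runif(2, -0.7, 0.7), runif(1, 10, 16))))
          p[3] <- min(p[3], L[3] - 2)
          nxt <- addNode(p)
          addEdge(cur, nxt, r["network"], "network_capillary")
          cur <- nxt
          nseg <- nseg + 1
        }
      }
      for (b in seq_len(nb)) {
        phi <- 2 * pi * (b - 0.5) / nb + runif(1, -0.2, 0.2)
        lat <- min(cw, ch) * 0.22
        bEnd <- clampXy(c(anchors[a, 1] + lat * cos(phi),
                          anchors[a, 2] + lat * sin(phi), 0))
        bEnd[3] <- 6 + stemLen + runif(1, 14, 22)
        bEnd <- pushOffHero(clampXy(bEnd))
        bNode <- addNode(bEnd)
        addEdge(stemEnd, bNode, r["branch"], "arteriole_branch")

        depth <- if (isHero && b == 1) max(spec@sheathBifurcationDepth)
                 else sampleRange(spec@sheathBifurcationDepth)
        if (depth == 0) {
          # unsheathed capillary straight into the network
          cur <- bNode
          for (s in 1:3) {
            p <- clampXy(nodes[cur, ] + c(runif(2, -9, 9), runif(1, 10, 16)))
            nxt <- addNode(p)
            addEdge(cur, nxt, r["network"], "network_capillary")
            cur <- nxt
          }
          netIds <- c(netIds, cur)
          next
        }

        built <- growSheathedPath(start = bNode, anchor = anchors[a, ],
                                  depth = depth, hero = isHero && b == 1,
                                  cellHalf = min(cw, ch) / 2 - 2)
        if (isHero && b == 1) hero <- built$hero

        # post-sheath continuation meandering down through the cords, so the
        # capillary network populates the deepest sections too.  The hero
        # path instead ends free (an open end in the cords): its exit is
        # then reachable only along the designed tube, which keeps the
        # entry-to-exit geodesic well defined
        if (isHero && b == 1) next
        cur <- built$exit
        linkable <- TRUE
        nseg <- 0
        while (nodes[cur, 3] < L[3] - 10 && nseg < 20) {
          p <- pushOffHero(clampXy(nodes[cur, ] + c(runif(2, -10, 10), runif(1, 10, 16))))
          p[3] <- min(p[3], L[3] - 2)
          nxt <- addNode(p)
          addEdge(cur, nxt, r["network"], "network_capillary")
          # short lateral twigs keep the cord network realistically dense
          if (nseg %% 2 == 0) {
            phi <- runif(1, 0, 2 * pi)
            tw <- pushOffHero(clampXy(p + c(14 * cos(phi), 14 * sin(phi), runif(1, 4, 9))))
            tw[3] <- min(tw[3], L[3] - 2)
            twId <- addNode(tw)
            addEdge(nxt, twId, r["network"], "network_capillary")
            tw2 <- pushOffHero(clampXy(tw + c(10 * cos(phi + 1), 10 * sin(phi + 1),
                                              runif(1, 6, 10))))
            tw2[3] <- min(tw2[3], L[3] - 2)
            tw2Id <- addNode(tw2)
            addEdge(twId, tw2Id, r["network"], "network_capillary")
          }
          cur <- nxt
          nseg <- nseg + 1
        }
        if (linkable) netIds <- c(netIds, cur)
      }
      networkNodes[[a]] <- netIds
    }

    # cross-link neighbouring arteriole networks (red pulp capillary mesh)
    allNet <- unlist(networkNodes)
    if (length(allNet) >= 2) {
      for (a in seq_len(max(0, spec@nArterioles - 1))) {
        i <- networkNodes[[a]]; j <- networkNodes[[a + 1]]
        if (length(i) == 0 || length(j) == 0) next
        d <- as.matrix(stats::dist(nodes[c(i[1], j[1]), , drop = FALSE]))[1, 2]
        if (d < 90) addEdge(i[1], j[1], r["network"], "network_capillary")
      }
    }

    # bypass capillaries: direct non-sheathed arteriole-to-network links
    # (attached to non-hero trees when possible, so the designed geodesic
    # path cannot be short-circuited)
    if (spec@nBypassCapillaries > 0) {
      branchNodes <- edges$to[edges$class == "arteriole_branch"]
      heroBranch <- if (length(hero) > 0) hero$entry else -1L
      pref <- c(setdiff(branchNodes, heroBranch), branchNodes)
      for (k in seq_len(spec@nBypassCapillaries)) {
        src <- pref[(k - 1) %% length(pref) + 1]
        p0 <- nodes[src, ]
        mid <- addNode(pushOffHero(clampXy(p0 + c(runif(2, -14, 14), runif(1, 18, 26)))))
        addEdge(src, mid, r["bypass"], "bypass_capillary")
        end <- addNode(pushOffHero(clampXy(nodes[mid, ] + c(runif(2, -10, 10), runif(1, 16, 22)))))
        addEdge(mid, end, r["bypass"], "bypass_capillary")
      }
    }
  }

  # venule with capillary contacts along the far-corner z column
  if (spec@nVenuleContacts > 0) {
    if (spec@nArterioles == 0)
      stop("infeasible phantom: venule contacts need a capillary network ",
           "(violated: n_arterioles > 0 when n_venule_contacts > 0)")
    vx <- L[1] - margin + 2
    vy <- L[2] - margin + 2
    vzs <- seq(10, L[3] - 10, length.out = 4)
    vids <- vapply(vzs, function(z) addNode(c(vx, vy, z)), integer(1))
    for (i in seq_len(length(vids) - 1))
      addEdge(vids[i], vids[i + 1], r["venule"], "venule")
    for (k in seq_len(spec@nVenuleContacts)) {
      vz <- runif(1, L[3] * 0.45, L[3] - 24)
      vn <- addNode(c(vx, vy, vz))
      # splice the venule node into the polyline nearest segment
      near <- which.min(abs(vzs - vz))
      addEdge(vids[near], vn, r["venule"], "venule")
      reach <- addNode(clampXy(c(vx - runif(1, 18, 26), vy - runif(1, 18, 26), vz)))
      addEdge(reach, vn, r["network"], "network_capillary", contact = TRUE)
    }
  }

  new("PhantomGroundTruth",
      nodes = nodes, edges = edges, sheaths = sheaths, bcells = bcells,
      stainMap = list(
        arteriole_stem = c("SMA", "CD34"), arteriole_branch = c("SMA", "CD34"),
        sheathed_capillary = "CD34", side_branch_open = "CD34",
        network_capillary = "CD34", bypass_capillary = "CD34",
        venule = "CD34", sheath = "CD271", bcell = "CD20"),
      heroPath = hero, domainSizeUm = L)
}

#' Ground-truth entry-to-exit geodesic of the designed sheathed path
#'
#' The workflow reports sheathed-path spans as geodesic distances measured on
#' the reconstructed vessel surface, so the phantom's reference value is
#' computed the same way: the designed path alone is voxelized at fine,
#' near-isotropic spacing directly from ground truth (no rendering,
#' registration or filtering involved), surfaced, and the on-surface
#' entry-to-exit distance is measured.  This is the value the reconstruction
#' pipeline is expected to reproduce.
#'
#' @param gt a \linkS4class{PhantomGroundTruth} with a designed path.
#' @param spacingUm voxelization spacing of the reference tube.
#' @return list(geodesicUm, centerlineUm).
#' @export
heroReferenceGeodesic <- function(gt, spacingUm = c(0.5, 0.5, 0.5)) {
  if (length(gt@heroPath) == 0) stop("phantom has no designed path")
  ids <- gt@heroPath$nodes
  P <- gt@nodes[ids, , drop = FALSE]
  rad <- gt@edges$radiusUm[gt@sheaths[[gt@heroPath$sheathId]]$edges[1]]
  segs <- cbind(P[-nrow(P), , drop = FALSE], P[-1, , drop = FALSE], rad)
  lo <- apply(P, 2, min) - rad - 3
  hi <- apply(P, 2, max) + rad + 3
  dims <- ceiling((hi - lo) / spacingUm)[c(2, 1, 3)]
  vol <- cpp_rasterize_capsules(array(0, dims), segs, spacingUm, lo, TRUE)
  cv <- new("ChannelVolume", values = vol * 255, spacingUm = spacingUm,
            originUm = lo, channel = "reference", provenance = "raw")
  mesh <- isosurface(cv, 127)
  segl <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  list(geodesicUm = geodesicPathLength(mesh, P[1, ], P[nrow(P), ]),
       centerlineUm = sum(segl))
}

#' Tally structure classes by walking a ground-truth graph
#'
#' Independent recount of edges per structure class and of derived quantities
#' (sheaths, open ends); used to cross-check \code{\link{buildPhantom}}.
#'
#' @param gt a \linkS4class{PhantomGroundTruth}.
#' @return named list of counts.
#' @export
tallyGroundTruth <- function(gt) {
  e <- gt@edges
  deg <- tabulate(c(e$from, e$to), nbins = nrow(gt@nodes))
  openEnds <- sum(e$class == "side_branch_open" &
                    (deg[e$to] == 1 | deg[e$from] == 1))
  list(
    edgesByClass = as.list(table(e$class)),
    nSheaths = length(gt@sheaths),
    nOpenSideBranches = openEnds,
    nBypassEdges = sum(e$class == "bypass_capillary"),
    nVenuleContacts = sum(e$venuleContact),
    nBcells = nrow(gt@bcells))
}

#' Voxelize ground truth into per-stain occupancy volumes
#'
#' Rasterizes vessel capsules, sheath shells and B-cell spheres into scalar
#' occupancy grids in [0, 1], one per stain.
#'
#' @param gt a \linkS4class{PhantomGroundTruth}.
#' @param spacingUm voxel spacing (x, y, z) in um.
#' @param soft logical; TRUE gives partial-volume (subvoxel ramp) occupancy,
#'   FALSE strict binary membership.
#' @param extentUm grid extent, default the phantom domain.
#' @param originUm grid origin, default the domain corner.
#' @return named list of (H, W, Z) arrays: SMA, CD34, CD271, CD20.
#' @export
voxelizeGroundTruth <- function(gt, spacingUm, soft = FALSE,
                                extentUm = gt@domainSizeUm,
                                originUm = c(0, 0, 0)) {
  stopifnot(all(spacingUm > 0))
  minr <- if (nrow(gt@edges) > 0) min(gt@edges$radiusUm) else Inf
  if (max(spacingUm) > minr)
    warning("voxel spacing coarser than the smallest vessel radius; ",
            "thin structures may vanish")
  dims <- c(
    max(1L, round(extentUm[2] / spacingUm[2])),
    max(1L, round(extentUm[1] / spacingUm[1])),
    max(1L, round(extentUm[3] / spacingUm[3])))
  blank <- array(0, dims)

  segMat <- function(classes) {
    e <- gt@edges[gt@edges$class %in% classes, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    cbind(gt@nodes[e$from, , drop = FALSE], gt@nodes[e$to, , drop = FALSE],
          e$radiusUm)
  }
  rast <- function(classes) {
    m <- segMat(classes)
    if (is.null(m)) return(blank)
    cpp_rasterize_capsules(blank, m, spacingUm, originUm, soft)
  }

  vessels <- c("arteriole_stem", "arteriole_branch", "sheathed_capillary",
               "side_branch_open", "network_capillary", "bypass_capillary",
               "venule")
  out <- list(
    SMA = rast(c("arteriole_stem", "arteriole_branch")),
    CD34 = rast(vessels),
    CD271 = blank,
    CD20 = blank)

  for (s in gt@sheaths) {
    e <- gt@edges[s$edges, , drop = FALSE]
    m <- cbind(gt@nodes[e$from, , drop = FALSE], gt@nodes[e$to, , drop = FALSE],
               e$radiusUm)
    out$CD271 <- cpp_rasterize_shell(out$CD271, m, s$innerRadiusUm,
                                     s$outerRadiusUm, spacingUm, originUm, soft)
  }
  if (nrow(gt@bcells) > 0) {
    m <- cbind(gt@bcells[, 1:3, drop = FALSE], gt@bcells[, 1:3, drop = FALSE],
               gt@bcells[, 4])
    out$CD20 <- cpp_rasterize_capsules(blank, m, spacingUm, originUm, soft)
  }
  out
}

#' Render a phantom into triple-stained serial sections
#'
#' Integrates per-stain occupancy through each 7-um slab, converts column
#' densities to transmitted RGB by Beer-Lambert mixing with the configured
#' stain matrix, alternates the third stain (even 0-based sections carry
#' CD271, odd carry CD20; SMA and CD34 are on every section), applies
#' per-section rigid jitter, and adds Gaussian pixel noise.  The renderer
#' uses the transmittance convention I = 256 * 10^(-OD) - 1, the exact
#' inverse of the unmixer's optical-density formula, so a zero-noise,
#' zero-jitter phantom round-trips through color deconvolution to machine
#' precision.
#'
#' @param gt a \linkS4class{PhantomGroundTruth}.
#' @param stain a \linkS4class{StainModel}.
#' @param spec the \linkS4class{PhantomSpec} describing the acquisition.
#' @return a \linkS4class{SectionStack} with jitter ground truth in metadata.
#' @export
renderSections <- function(gt, stain, spec) {
  validObject(stain)
  L <- spec@domainSizeUm
  px <- spec@pixelSizeUm
  th <- spec@sectionThicknessUm
  nsec <- floor(L[3] / th)
  if (nsec < 1) stop("domain thinner than one section")
  zsub <- 1  # um substep for slab integration
  occ <- voxelizeGroundTruth(gt, c(px, px, zsub), soft = TRUE)
  nsub <- round(th / zsub)
  M <- stain@odMatrix
  amp <- stain@concentrationScale

  with_seed(derive_seed(spec@seed, "render"), function() {
    jit <- data.frame(theta = numeric(nsec), tx = numeric(nsec), ty = numeric(nsec))
    sectionsL <- vector("list", nsec)
    H <- dim(occ$CD34)[1]; W <- dim(occ$CD34)[2]
    slab <- function(vol, k) {
      idx <- (k * nsub + 1):((k + 1) * nsub)
      idx <- idx[idx <= dim(vol)[3]]
      Reduce(`+`, lapply(idx, function(j) vol[, , j])) / length(idx)
    }
    for (k in seq_len(nsec) - 1L) {
      red <- if (k %% 2 == 0) "CD271" else "CD20"
      A <- cbind(brown = as.vector(slab(occ$SMA, k)) * amp["SMA"],
                 blue = as.vector(slab(occ$CD34, k)) * amp["CD34"],
                 red = as.vector(slab(occ[[red]], k)) * amp[red])
      rgb <- beerLambertRgb(A, M)
      img <- array(rgb, c(H, W, 3))
      theta <- stats::runif(1, -1, 1) * spec@jitterRotationDeg * pi / 180
      tx <- stats::runif(1, -1, 1) * spec@jitterTranslationPx
      ty <- stats::runif(1, -1, 1) * spec@jitterTranslationPx
      jit[k + 1, ] <- c(theta, tx, ty)
      if (abs(theta) > 0 || abs(tx) > 0 || abs(ty) > 0) {
        for (c in 1:3)
          img[, , c] <- cpp_warp_rigid(img[, , c], theta, tx, ty, 255)
      }
      if (spec@noiseSd > 0) {
        img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd), dim(img))
        img[img < 0] <- 0; img[img > 255] <- 255
      }
      sectionsL[[k + 1]] <- new("SectionImage", pixels = img,
                                pixelSizeUm = px, sectionIndex = k,
                                zUm = k * th,
                                stainSet = c("SMA", "CD34", red),
                                focusOk = TRUE)
    }
    new("SectionStack", sections = sectionsL, thicknessUm = th, jitter = jit,
        lostSections = integer(0),
        meta = list(seed = spec@seed, parity = "CD271_even",
                    pixelSizeUm = px, domainSizeUm = L))
  })
}

#' Apply section-loss and defocus artifacts to a stack
#'
#' Lost sections are removed from the series (their 0-based indices recorded
#' in metadata; surviving sections keep their original index and z); defocused
#' sections are Gaussian-blurred and flagged.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param lostSectionIndices 0-based section indices to drop.
#' @param defocusIndices 0-based section indices to blur.
#' @param defocusSigma blur sigma in pixels.
#' @return the modified stack.
#' @export
applySectionArtifacts <- function(stack, lostSectionIndices = integer(0),
                                  defocusIndices = integer(0),
                                  defocusSigma = 3) {
  idx <- vapply(stack@sections, function(s) s@sectionIndex, integer(1))
  bad <- setdiff(c(lostSectionIndices, defocusIndices), idx)
  if (length(bad) > 0)
    stop("section indices out of range: ", paste(bad, collapse = ", "))
  secs <- stack@sections
  for (i in seq_along(secs)) {
    if (secs[[i]]@sectionIndex %in% defocusIndices) {
      img <- secs[[i]]@pixels
      for (c in 1:3) {
        ch <- img[, , c]
        dim(ch) <- c(dim(img)[1], dim(img)[2], 1)
        img[, , c] <- cpp_gauss3d(ch, c(defocusSigma, defocusSigma, 0))
      }
      secs[[i]]@pixels <- img
      secs[[i]]@focusOk <- FALSE
    }
  }
  keep <- !(idx %in% lostSectionIndices)
  jit <- stack@jitter
  if (nrow(jit) == length(secs)) jit <- jit[keep, , drop = FALSE]
  new("SectionStack", sections = secs[keep], thicknessUm = stack@thicknessUm,
      jitter = jit,
      lostSections = sort(unique(c(stack@lostSections,
                                   as.integer(lostSectionIndices)))),
      meta = stack@meta)
}
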