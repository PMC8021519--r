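# shared fixtures built in code

# digitized ball volumes on an n^3 grid, radius r voxels
ballVolume <- function(n = 48, r = 20, binary = TRUE, spacing = c(1, 1, 1)) {
  ctr <- (n - 1) / 2
  ax <- 0:(n - 1)
  d <- sqrt(outer(outer((ax - ctr)^2, (ax - ctr)^2, "+"), (ax - ctr)^2, "+"))
  v <- if (binary) ifelse(d <= r, 255, 0) else 255 * pmin(1, pmax(0, 0.5 + (r - d)))
  new("ChannelVolume", values = array(v, c(n, n, n)), spacingUm = spacing,
      originUm = c(0, 0, 0), channel = "test", provenance = "raw")
}

# closed icosphere-like mesh: subdivided octahedron projected to a sphere
sphereMesh <- function(radius = 10, center = c(0, 0, 0), subdiv = 3) {
  V <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  F <- rbind(c(1,3,5), c(3,2,5), c(2,4,5), c(4,1,5),
             c(3,1,6), c(2,3,6), c(4,2,6), c(1,4,6))
  for (s in seq_len(subdiv)) {
    nv <- nrow(V)
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    getmid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid[[k]] <- nrow(V)
      nrow(V)
    }
    F2 <- NULL
    for (f in seq_len(nrow(F))) {
      a <- F[f,1]; b <- F[f,2]; cc <- F[f,3]
      ab <- getmid(a,b); bc <- getmid(b,cc); ca <- getmid(cc,a)
      F2 <- rbind(F2, c(a,ab,ca), c(ab,b,bc), c(ca,bc,cc), c(ab,bc,ca))
    }
    F <- F2
  }
  makeMesh(sweep(V * radius, 2, center, "+"), F, "test")
}

# open cylinder mesh along z (no end caps)
openCylinderMesh <- function(radius = 5, length = 40, nseg = 24, nz = 16) {
  th <- seq(0, 2*pi, length.out = nseg + 1)[-1]
  zs <- seq(0, length, length.out = nz)
  V <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  F <- NULL
  for (iz in seq_len(nz - 1)) {
    for (it in seq_len(nseg)) {
      a <- (iz-1)*nseg + it
      b <- (iz-1)*nseg + (it %% nseg) + 1
      cc <- iz*nseg + it
      d <- iz*nseg + (it %% nseg) + 1
      F <- rbind(F, c(a, b, cc), c(b, d, cc))
    }
  }
  makeMesh(V, F, "test")
}

# axis-aligned rectangle mesh (two triangles) in the plane z = z0
planeMesh <- function(z0, size = 50) {
  V <- rbind(c(0,0,z0), c(size,0,z0), c(size,size,z0), c(0,size,z0))
  makeMesh(V, rbind(c(1,2,3), c(1,3,4)), "test")
}

# a small, fast phantom spec for tests that do not need the full desk scale
tinySpec <- function(...) {
  phantomSpec(domainSizeUm = c(96, 96, 168), nArterioles = 1L,
              branchesPerArteriole = c(1L, 1L),
              sheathBifurcationDepth = c(2L, 2L),
              nBypassCapillaries = 1L, nVenuleContacts = 1L,
              bcellDensity = 2, ...)
}

meshVolumeSigned <- function(mesh) meshVolume(mesh)
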