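# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

# exhaustive Otsu: try every candidate threshold with explicit class
# moments; a tied plateau resolves to its middle candidate
oracle_otsu <- function(img) {
  v <- as.vector(img)
  s <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s[t + 1L] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  ties <- which(s == max(s))
  as.integer(floor(stats::median(ties))) - 1L
}

# naive Lloyd iteration on a numeric vector, explicit loops
oracle_lloyd <- function(x, centers, max_iter = 20L) {
  assign_prev <- rep(0L, length(x))
  iter <- 0L
  repeat {
    assign_cur <- integer(length(x))
    for (i in seq_along(x)) {
      dd <- abs(x[i] - centers)
      assign_cur[i] <- which(dd == min(dd))[1L]
    }
    if (all(assign_cur == assign_prev)) break
    if (iter >= max_iter) break
    iter <- iter + 1L
    for (j in seq_along(centers)) {
      xs <- x[assign_cur == j]
      if (length(xs)) centers[j] <- sum(xs) / length(xs)
    }
    assign_prev <- assign_cur
  }
  list(centers = centers, assignment = assign_cur)
}

# naive pair-counting GLCM, double loop over every pixel
oracle_glcm <- function(q, ng, offset = c(0L, 1L), symmetric = TRUE) {
  counts <- matrix(0, ng, ng)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1L]; c2 <- c + offset[2L]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- q[r, c]; b <- q[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# naive evaluation of all 23 traits from p(i,j), straight from the
# formula sheet (default corrections), scalar loops throughout
oracle_features <- function(p, eps = 2.2e-16) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  var_x <- 0; var_y <- 0
  for (i in 1:ng) {
    var_x <- var_x + (i - mu_x)^2 * px[i]
    var_y <- var_y + (i - mu_y)^2 * py[i]
  }
  pxy_sum <- numeric(2 * ng - 1)   # k = 2..2Ng at index k-1
  pxy_dif <- numeric(ng)           # k = 0..Ng-1 at index k+1
  for (i in 1:ng) for (j in 1:ng) {
    pxy_sum[i + j - 1] <- pxy_sum[i + j - 1] + p[i, j]
    pxy_dif[abs(i - j) + 1] <- pxy_dif[abs(i - j) + 1] + p[i, j]
  }
  mu_sum <- 0
  for (k in 2:(2 * ng)) mu_sum <- mu_sum + k * pxy_sum[k - 1]
  mu_dif <- 0
  for (k in 0:(ng - 1)) mu_dif <- mu_dif + k * pxy_dif[k + 1]
  HX <- 0; HY <- 0
  for (i in 1:ng) {
    HX <- HX - px[i] * log2(px[i] + eps)
    HY <- HY - py[i] * log2(py[i] + eps)
  }
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    HXY <- HXY - p[i, j] * log2(p[i, j] + eps)
    HXY1 <- HXY1 - p[i, j] * log2(px[i] * py[j] + eps)
    HXY2 <- HXY2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
  }
  autoc <- 0; contr <- 0; cprom <- 0; cshad <- 0; dissi <- 0
  energ <- 0; entro <- 0; homom <- 0; homop <- 0
  sosvh <- 0; indnc <- 0; idmnc <- 0; num_corrm <- 0
  for (i in 1:ng) for (j in 1:ng) {
    autoc <- autoc + i * j * p[i, j]
    contr <- contr + (i - j)^2 * p[i, j]
    num_corrm <- num_corrm + (i - mu_x) * (j - mu_y) * p[i, j]
    cprom <- cprom + (i - mu_x + j - mu_y)^4 * p[i, j]
    cshad <- cshad + (i - mu_x + j - mu_y)^3 * p[i, j]
    dissi <- dissi + abs(i - j) * p[i, j]
    energ <- energ + p[i, j]^2
    entro <- entro - p[i, j] * log2(p[i, j] + eps)
    homom <- homom + p[i, j] / (1 + (i - j)^2)
    homop <- homop + p[i, j] / (1 + abs(i - j))
    sosvh <- sosvh + (i - mu_x)^2 * p[i, j]
    indnc <- indnc + p[i, j] / (1 + abs(i - j) / ng)
    idmnc <- idmnc + p[i, j] / (1 + (i - j)^2 / ng)
  }
  sig <- sqrt(var_x * var_y)
  corrm <- if (sig > 0) num_corrm / sig else NaN
  corrp <- if (sig > 0) (autoc - mu_x * mu_y) / sig else NaN
  savgh <- 0; svarh <- 0; senth <- 0
  for (k in 2:(2 * ng)) {
    savgh <- savgh + k * pxy_sum[k - 1]
    svarh <- svarh + (k - mu_sum)^2 * pxy_sum[k - 1]
    senth <- senth - pxy_sum[k - 1] * log2(pxy_sum[k - 1] + eps)
  }
  dvarh <- 0; denth <- 0
  for (k in 0:(ng - 1)) {
    dvarh <- dvarh + (k - mu_dif)^2 * pxy_dif[k + 1]
    denth <- denth - pxy_dif[k + 1] * log2(pxy_dif[k + 1] + eps)
  }
  c(autoc = autoc, contr = contr, corrm = corrm, corrp = corrp,
    cprom = cprom, cshad = cshad, dissi = dissi, energ = energ,
    entro = entro, homom = homom, homop = homop, maxpr = max(p),
    sosvh = sosvh, savgh = savgh, svarh = svarh, senth = senth,
    dvarh = dvarh, denth = denth,
    inf1h = (HXY - HXY1) / max(HX, HY),
    inf2h = 1 - exp(-2 * (HXY2 - HXY)),
    homom1 = homop, indnc = indnc, idmnc = idmnc)
}

# random normalized GLCM-like probability matrix
random_prob_matrix <- function(ng) {
  m <- matrix(stats::runif(ng * ng), ng, ng)
  m <- m + t(m)
  m / sum(m)
}

# tiny three-strata scene assembled by hand (not via canopy_scene)
hand_scene <- function(w = 40, h = 30, canopy_value = 60) {
  img <- matrix(0, h, w)
  pot <- matrix(FALSE, h, w); pot[25:28, 10:30] <- TRUE
  canopy <- matrix(FALSE, h, w); canopy[5:18, 12:28] <- TRUE
  img[pot] <- rep_len(11:17, sum(pot))
  img[canopy] <- canopy_value
  list(image = img, canopy = canopy + 0L, pot = pot + 0L)
}
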