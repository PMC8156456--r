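# Batched CSFAG layer used inside skip connections, with a hand-derived
# backward pass.  The layer wraps the functional filter with learnable
# transforms: a 3x3 guide transform (encoder feature -> m channels), a 3x3
# filter transform (deeper decoder feature -> m channels), the fused
# attention branch, the attention-weighted fast guided filter itself
# (radius r, ridge lambda), and a 3x3 output transform back to the skip
# width.  The filtered map lives at half the guide's resolution
# (subsample factor 2 inside skips).

nn_csfag <- function(cg_in, cf_in, m, cout, r = 4L, lambda = 0.001,
                     rho = 16L, ks = 7L, weighted = TRUE) {
  mod <- new_module("csfag")
  mod$m <- as.integer(m); mod$r <- as.integer(r); mod$lambda <- lambda
  mod$weighted <- isTRUE(weighted)
  mod$children$gconv <- nn_conv(cg_in, m)
  mod$children$fconv <- nn_conv(cf_in, m)
  mod$children$attn <- nn_csfag_attn(m, rho, ks)
  mod$children$outconv <- nn_conv(m, cout)
  mod
}

csfag_layer_forward <- function(mod, G_in, F_in, training = FALSE) {
  Gp <- nn_forward(mod$children$gconv, G_in, training)
  Fp <- nn_forward(mod$children$fconv, F_in, training)
  dG <- dim(Gp); dF <- dim(Fp)
  H <- dG[1]; W <- dG[2]; m <- dG[3]; N <- dG[4]
  h <- dF[1]; w <- dF[2]
  r <- mod$r; lam <- mod$lambda
  Gl <- bilinear_resize(Gp, h, w)
  att <- csfag_attn_forward(mod$children$attn, Fp, Gl, training)
  A <- att$A                                           # (h, w, 1, N)
  if (mod$weighted) {
    a <- A^2
    S <- boxsum(a, r)
    ab <- bcast_ch(a, m)
    Sb <- bcast_ch(S, m)
  } else {
    cnt1 <- array(rep(box_counts(h, w, r), N), dim = c(h, w, 1L, N))
    a <- array(1, dim = c(h, w, 1L, N))
    S <- cnt1
    ab <- array(1, dim = dF)
    Sb <- bcast_ch(cnt1, m)
  }
  mG <- boxsum(ab * Gl, r) / Sb
  mF <- boxsum(ab * Fp, r) / Sb
  mGF <- boxsum(ab * Gl * Fp, r) / Sb
  mGG <- boxsum(ab * Gl * Gl, r) / Sb
  var_raw <- mGG - mG^2
  clamped <- var_raw < 0
  va <- pmax(var_raw, 0)
  cov <- mGF - mG * mF
  Wk <- cov / (va + lam)
  Bk <- mF - Wk * mG
  NinvB <- bcast_ch(array(rep(1 / box_counts(h, w, r), N),
                          dim = c(h, w, 1L, N)), m)
  Wl <- boxsum(Wk, r) * NinvB
  Bl <- boxsum(Bk, r) * NinvB
  Wh <- bilinear_resize(Wl, H, W)
  Bh <- bilinear_resize(Bl, H, W)
  O <- Wh * Gp + Bh
  out <- nn_forward(mod$children$outconv, O, training)
  mod$cache <- list(Gp = Gp, Fp = Fp, Gl = Gl, A = A, ab = ab, Sb = Sb,
                    mG = mG, mF = mF, mGF = mGF, mGG = mGG, va = va,
                    cov = cov, Wk = Wk, clamped = clamped, NinvB = NinvB,
                    Wh = Wh, Hh = c(H, W), hw = c(h, w))
  out
}

csfag_layer_backward <- function(mod, dout) {
  cc <- mod$cache
  r <- mod$r; lam <- mod$lambda
  H <- cc$Hh[1]; W <- cc$Hh[2]; h <- cc$hw[1]; w <- cc$hw[2]
  m <- dim(cc$Gp)[3]
  dO <- nn_backward(mod$children$outconv, dout)
  dWh <- dO * cc$Gp
  dGp <- dO * cc$Wh
  dWl <- bilinear_resize_backward(dWh, h, w)
  dBl <- bilinear_resize_backward(dO, h, w)
  dWk <- boxsum(dWl * cc$NinvB, r)
  dBk <- boxsum(dBl * cc$NinvB, r)
  dmF <- dBk
  dWk2 <- dWk - dBk * cc$mG
  dmG <- -dBk * cc$Wk
  den <- cc$va + lam
  dcov <- dWk2 / den
  dvar <- -dWk2 * cc$cov / den^2
  dvar[cc$clamped] <- 0
  dmGF <- dcov
  dmG <- dmG - dcov * cc$mF
  dmF <- dmF - dcov * cc$mG
  dmGG <- dvar
  dmG <- dmG - 2 * cc$mG * dvar
  Gl <- cc$Gl; Fp <- cc$Fp; ab <- cc$ab; Sb <- cc$Sb
  PG <- boxsum(dmG / Sb, r)
  PF <- boxsum(dmF / Sb, r)
  PGF <- boxsum(dmGF / Sb, r)
  PGG <- boxsum(dmGG / Sb, r)
  dGl <- ab * (PG + Fp * PGF + 2 * Gl * PGG)
  dFp <- ab * (PF + Gl * PGF)
  if (mod$weighted) {
    da_ch <- Gl * PG + Fp * PF + Gl * Fp * PGF + Gl * Gl * PGG
    dS_ch <- -(cc$mG * dmG + cc$mF * dmF + cc$mGF * dmGF +
                 cc$mGG * dmGG) / Sb
    sum_ch <- function(z) {
      out <- z[, , 1, , drop = FALSE]
      if (m > 1) for (ch in 2:m) out <- out + z[, , ch, , drop = FALSE]
      out
    }
    dS <- sum_ch(dS_ch)
    da <- sum_ch(da_ch) + boxsum(dS, r)
    dA <- 2 * cc$A * da
    datt <- csfag_attn_backward(mod$children$attn, dA)
    dFp <- dFp + datt$dF
    dGl <- dGl + datt$dGl
  }
  dGp <- dGp + bilinear_resize_backward(dGl, H, W)
  list(dG = nn_backward(mod$children$gconv, dGp),
       dF = nn_backward(mod$children$fconv, dFp))
}
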