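// Second-order TGV regularized SENSE reconstruction by a first-order
// primal-dual (Chambolle-Pock type) iteration, plus the centered unitary
// 3D FFT it is built on. Complex throughout; magnitude is taken in R at
// export time only.
//
// Encoding model per coil c:  A_c u = mask .* F( m_c .* u )
// with F the centered unitary FFT (DC at floor(N/2), 0-based) and m_c the
// coil sensitivity. The solver approximately minimizes
//   lambda/2 * sum_c ||A_c u - f_c||^2 + a1*||grad(u) - v||_1 + a0*||E(v)||_1
// over complex image u and complex vector field v, E the symmetrized
// gradient. Gradients are forward differences with Neumann boundary.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// ---- FFT ------------------------------------------------------------------

static cx_cube fft3_raw(const cx_cube& x, bool inverse) {
  uword n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  cx_cube out = x;
  for (uword s = 0; s < n3; ++s) {
    if (inverse) out.slice(s) = cx_mat(ifft2(out.slice(s))) *
      static_cast<double>(n1 * n2);            // undo arma's 1/N scaling
    else         out.slice(s) = cx_mat(fft2(out.slice(s)));
  }
  if (n3 > 1) {
    cx_mat tmp(n3, n1 * n2);
    for (uword s = 0; s < n3; ++s) tmp.row(s) = vectorise(out.slice(s)).st();
    if (inverse) tmp = cx_mat(ifft(tmp)) * static_cast<double>(n3);
    else         tmp = cx_mat(fft(tmp));
    for (uword s = 0; s < n3; ++s)
      out.slice(s) = reshape(tmp.row(s).st(), n1, n2);
  }
  return out;
}

static cx_cube circshift3(const cx_cube& x, int s1, int s2, int s3) {
  uword n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  cx_cube out(n1, n2, n3);
  auto wrap = [](int i, int s, int n) { return ((i + s) % n + n) % n; };
  for (uword k = 0; k < n3; ++k) {
    uword kk = wrap(k, s3, n3);
    for (uword j = 0; j < n2; ++j) {
      uword jj = wrap(j, s2, n2);
      for (uword i = 0; i < n1; ++i)
        out(wrap(i, s1, n1), jj, kk) = x(i, j, k);
    }
  }
  return out;
}

// centered unitary transform: DC at floor(N/2) per axis (0-based)
static cx_cube fft3c(const cx_cube& x, bool inverse) {
  int h1 = x.n_rows / 2, h2 = x.n_cols / 2, h3 = x.n_slices / 2;
  cx_cube y = circshift3(x, -h1, -h2, -h3);
  y = fft3_raw(y, inverse);
  y = circshift3(y, h1, h2, h3);
  return y / std::sqrt(static_cast<double>(x.n_elem));
}

// [[Rcpp::export]]
arma::cx_cube cpp_fft3(const arma::cx_cube& x, bool inverse) {
  return fft3_raw(x, inverse);
}

// ---- differential operators ----------------------------------------------

// forward difference along dim (0,1,2), Neumann: last entry 0
static cx_cube gradd(const cx_cube& x, int dim) {
  uword n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  cx_cube g(n1, n2, n3, fill::zeros);
  if (dim == 0 && n1 > 1)
    g.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1) =
      x.subcube(1, 0, 0, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1);
  else if (dim == 1 && n2 > 1)
    g.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1) =
      x.subcube(0, 1, 0, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1);
  else if (dim == 2 && n3 > 1)
    g.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2) =
      x.subcube(0, 0, 1, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2);
  return g;
}

// exact adjoint of gradd
static cx_cube gradt(const cx_cube& p, int dim) {
  uword n1 = p.n_rows, n2 = p.n_cols, n3 = p.n_slices;
  cx_cube out(n1, n2, n3, fill::zeros);
  if (dim == 0 && n1 > 1) {
    out.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1) =
      -p.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1);
    out.subcube(1, 0, 0, n1 - 1, n2 - 1, n3 - 1) +=
      p.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1);
  } else if (dim == 1 && n2 > 1) {
    out.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1) =
      -p.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1);
    out.subcube(0, 1, 0, n1 - 1, n2 - 1, n3 - 1) +=
      p.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1);
  } else if (dim == 2 && n3 > 1) {
    out.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2) =
      -p.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2);
    out.subcube(0, 0, 1, n1 - 1, n2 - 1, n3 - 1) +=
      p.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2);
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_cube cpp_grad(const arma::cx_cube& x, int dim) { return gradd(x, dim); }

// [[Rcpp::export]]
arma::cx_cube cpp_grad_adj(const arma::cx_cube& p, int dim) { return gradt(p, dim); }

// symmetrized gradient: 6 components 11,22,33,12,13,23
static void symgrad(const std::vector<cx_cube>& v, std::vector<cx_cube>& e) {
  e[0] = gradd(v[0], 0);
  e[1] = gradd(v[1], 1);
  e[2] = gradd(v[2], 2);
  e[3] = 0.5 * (gradd(v[1], 0) + gradd(v[0], 1));
  e[4] = 0.5 * (gradd(v[2], 0) + gradd(v[0], 2));
  e[5] = 0.5 * (gradd(v[2], 1) + gradd(v[1], 2));
}

// adjoint of symgrad: (E^T q)_b = Gb^T q_bb + sum_{a != b} Ga^T q_ab
static void symgrad_adj(const std::vector<cx_cube>& q, std::vector<cx_cube>& w) {
  w[0] = gradt(q[0], 0) + gradt(q[3], 1) + gradt(q[4], 2);
  w[1] = gradt(q[1], 1) + gradt(q[3], 0) + gradt(q[5], 2);
  w[2] = gradt(q[2], 2) + gradt(q[4], 0) + gradt(q[5], 1);
}

// ---- proximal maps --------------------------------------------------------

// pointwise projection of an n-component complex field onto |.|_2 <= alpha,
// with component weights in the norm (off-diagonal doubling for symmetric
// tensors): |x| = sqrt(sum_k w_k |x_k|^2)
static void project_ball(std::vector<cx_cube>& x, const std::vector<double>& w,
                         double alpha) {
  cube nrm(x[0].n_rows, x[0].n_cols, x[0].n_slices, fill::zeros);
  for (size_t k = 0; k < x.size(); ++k)
    nrm += w[k] * square(abs(x[k]));
  nrm = sqrt(nrm) / alpha;
  nrm.transform([](double t) { return t > 1.0 ? t : 1.0; });
  cx_cube cnrm = conv_to<cx_cube>::from(nrm);
  for (size_t k = 0; k < x.size(); ++k) x[k] /= cnrm;
}

// [[Rcpp::export]]
Rcpp::List cpp_project_l2ball(Rcpp::List comps, Rcpp::NumericVector weights,
                              double alpha) {
  // assignment (not move) so each cube owns its memory: the converted
  // cubes borrow R's buffers and must not be modified in place
  std::vector<cx_cube> x(comps.size());
  std::vector<double> w(comps.size());
  for (int k = 0; k < comps.size(); ++k) {
    x[k] = Rcpp::as<cx_cube>(comps[k]);
    w[k] = weights[k];
  }
  project_ball(x, w, alpha);
  Rcpp::List out(comps.size());
  for (int k = 0; k < comps.size(); ++k) out[k] = x[k];
  return out;
}

// resolvent of the convex-conjugate data term:
// r <- (r + sigma*(Au - f)) / (1 + sigma/lambda)
// [[Rcpp::export]]
arma::cx_cube cpp_prox_data_dual(const arma::cx_cube& r, const arma::cx_cube& Au,
                                 const arma::cx_cube& f, double sigma,
                                 double lambda) {
  return (r + sigma * (Au - f)) / (1.0 + sigma / lambda);
}

// ---- SENSE operator -------------------------------------------------------
//
// Inside the solver the k-space is kept in DC-at-origin layout with the
// centering phase demodulated (for even axes a (-1)^k checkerboard), so the
// hot loop uses plain unitary FFTs with no circular shifts; the image-domain
// solution is unaffected. The data are premultiplied by the conjugate phase
// once on entry.

struct Sense {
  const std::vector<cx_cube>* maps;
  cube maskS;          // ifftshifted 0/1 mask
  double inv_sqrtN;

  void apply_mask(cx_cube& x) const {
    const double* mp = maskS.memptr();
    cx_double* xp = x.memptr();
    for (uword i = 0; i < x.n_elem; ++i) if (mp[i] == 0.0) xp[i] = 0.0;
  }
  cx_cube fwd(const cx_cube& u, size_t c) const {
    cx_cube out = fft3_raw((*maps)[c] % u, false);
    out *= inv_sqrtN;
    apply_mask(out);
    return out;
  }
  void adj_accum(const std::vector<cx_cube>& r, cx_cube& out,
                 cx_cube& buf) const {
    out.zeros();
    for (size_t c = 0; c < maps->size(); ++c) {
      buf = r[c];
      apply_mask(buf);
      buf = fft3_raw(buf, true);
      out += conj((*maps)[c]) % buf * inv_sqrtN;
    }
  }
};

static double norm2sq(const cx_cube& x) { return accu(square(abs(x))); }

// in-place forward difference into preallocated g (Neumann: last entry 0)
static void gradd_into(const cx_cube& x, int dim, cx_cube& g) {
  g.zeros();
  uword n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  if (dim == 0 && n1 > 1)
    g.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1) =
      x.subcube(1, 0, 0, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 2, n2 - 1, n3 - 1);
  else if (dim == 1 && n2 > 1)
    g.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1) =
      x.subcube(0, 1, 0, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 1, n2 - 2, n3 - 1);
  else if (dim == 2 && n3 > 1)
    g.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2) =
      x.subcube(0, 0, 1, n1 - 1, n2 - 1, n3 - 1) -
      x.subcube(0, 0, 0, n1 - 1, n2 - 1, n3 - 2);
}

// pointwise projection with preallocated norm buffer
static void project_ball_buf(std::vector<cx_cube>& x,
                             const std::vector<double>& w, double alpha,
                             cube& nrm) {
  nrm.zeros();
  for (size_t k = 0; k < x.size(); ++k)
    nrm += w[k] * square(abs(x[k]));
  double* np = nrm.memptr();
  for (uword i = 0; i < nrm.n_elem; ++i) {
    double t = std::sqrt(np[i]) / alpha;
    np[i] = t > 1.0 ? 1.0 / t : 1.0;
  }
  for (size_t k = 0; k < x.size(); ++k) {
    cx_double* xp = x[k].memptr();
    for (uword i = 0; i < nrm.n_elem; ++i) xp[i] *= np[i];
  }
}

// ---- solver ---------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_tgv2(Rcpp::List f_list, Rcpp::List maps_list,
                    const arma::cube& mask, double lambda, double alpha1,
                    double alpha0, int n_iter, int check_every, double tol,
                    int power_iter, int cg_warmup, double step_ratio) {
  size_t nc = f_list.size();
  std::vector<cx_cube> f(nc), maps(nc);
  for (size_t c = 0; c < nc; ++c) {
    f[c] = Rcpp::as<cx_cube>(f_list[c]);
    maps[c] = Rcpp::as<cx_cube>(maps_list[c]);
    if (!f[c].is_finite() || !maps[c].is_finite())
      Rcpp::stop("non-finite input to the solver");
  }
  uword n1 = mask.n_rows, n2 = mask.n_cols, n3 = mask.n_slices;
  int h1 = n1 / 2, h2 = n2 / 2, h3 = n3 / 2;

  // demodulate: f_int = conj(phi) .* ifftshift(f); phi(k) = e^{2i pi sum k h / n}
  cx_cube demod(n1, n2, n3);
  for (uword k = 0; k < n3; ++k)
    for (uword j = 0; j < n2; ++j)
      for (uword i = 0; i < n1; ++i) {
        double ph = 2.0 * datum::pi *
          (double(i) * h1 / n1 + double(j) * h2 / n2 + double(k) * h3 / n3);
        demod(i, j, k) = cx_double(std::cos(ph), -std::sin(ph));
      }
  for (size_t c = 0; c < nc; ++c)
    f[c] = demod % circshift3(f[c], -h1, -h2, -h3);
  cube maskS(n1, n2, n3);
  {
    cx_cube cm = circshift3(conv_to<cx_cube>::from(mask), -h1, -h2, -h3);
    maskS = real(cm);
  }
  Sense A{&maps, maskS, 1.0 / std::sqrt(double(n1 * n2 * n3))};

  // operator norm of K(u,v) = (grad u - v, E v, A u) by power method
  cx_cube pu(n1, n2, n3); pu.fill(cx_double(1.0, 0.0));
  std::vector<cx_cube> pv(3, cx_cube(n1, n2, n3));
  for (int b = 0; b < 3; ++b) pv[b].fill(cx_double(0.3, 0.1));
  double L = 1.0;
  {
    std::vector<cx_cube> e(6), w(3), pp(3);
    cx_cube nu(n1, n2, n3), buf(n1, n2, n3);
    double L_prev = 0.0;
    for (int it = 0; it < power_iter; ++it) {
      for (int b = 0; b < 3; ++b) pp[b] = gradd(pu, b) - pv[b];
      symgrad(pv, e);
      std::vector<cx_cube> r(nc);
      for (size_t c = 0; c < nc; ++c) r[c] = A.fwd(pu, c);
      A.adj_accum(r, nu, buf);
      for (int b = 0; b < 3; ++b) nu += gradt(pp[b], b);
      symgrad_adj(e, w);
      std::vector<cx_cube> nv(3);
      for (int b = 0; b < 3; ++b) nv[b] = w[b] - pp[b];
      double nrm = norm2sq(nu);
      for (int b = 0; b < 3; ++b) nrm += norm2sq(nv[b]);
      nrm = std::sqrt(nrm);
      L = std::sqrt(nrm);
      pu = nu / nrm;
      for (int b = 0; b < 3; ++b) pv[b] = nv[b] / nrm;
      if (it >= 10 && std::abs(L - L_prev) < 5e-4 * L) break;
      L_prev = L;
    }
  }
  double step = 1.0 / (1.08 * L);
  double tau = step * step_ratio, sigma = step / step_ratio;

  // warm start: zero-filled, optionally refined by CG on the data term
  cx_cube u(n1, n2, n3), buf(n1, n2, n3);
  u.zeros();
  A.adj_accum(f, u, buf);
  if (cg_warmup > 0) {
    cx_cube b = u, res = b, pdir = b, Ap(n1, n2, n3);
    u.zeros();
    double rs = norm2sq(res);
    std::vector<cx_cube> kbuf(nc, cx_cube(n1, n2, n3));
    for (int it = 0; it < cg_warmup && rs > 1e-30; ++it) {
      for (size_t c = 0; c < nc; ++c) kbuf[c] = A.fwd(pdir, c);
      A.adj_accum(kbuf, Ap, buf);
      double pAp = std::real(accu(conj(pdir) % Ap));
      if (pAp <= 0) break;
      double al = rs / pAp;
      u += al * pdir;
      res -= al * Ap;
      double rs2 = norm2sq(res);
      pdir = res + (rs2 / rs) * pdir;
      rs = rs2;
    }
  }
  std::vector<cx_cube> v(3, cx_cube(n1, n2, n3, fill::zeros));
  std::vector<cx_cube> p(3, cx_cube(n1, n2, n3, fill::zeros));
  std::vector<cx_cube> q(6, cx_cube(n1, n2, n3, fill::zeros));
  std::vector<cx_cube> r(nc, cx_cube(n1, n2, n3, fill::zeros));
  cx_cube ubar = u, unew(n1, n2, n3), gu(n1, n2, n3), gbuf(n1, n2, n3);
  std::vector<cx_cube> vbar = v, vnew(3, cx_cube(n1, n2, n3));
  std::vector<cx_cube> e(6, cx_cube(n1, n2, n3)), w3(3);
  cube nbuf(n1, n2, n3);

  const std::vector<double> wp = {1, 1, 1};
  const std::vector<double> wq = {1, 1, 1, 2, 2, 2};
  const double rfac = 1.0 / (1.0 + sigma / lambda);

  std::vector<double> tr_it, tr_en, tr_ch;
  int n_increase = 0;
  double last_energy = datum::inf;
  bool diverged = false;
  int iters_done = n_iter;

  for (int it = 1; it <= n_iter; ++it) {
    // dual updates
    for (int b = 0; b < 3; ++b) {
      gradd_into(ubar, b, gbuf);
      p[b] += sigma * (gbuf - vbar[b]);
    }
    project_ball_buf(p, wp, alpha1, nbuf);
    symgrad(vbar, e);
    for (int k = 0; k < 6; ++k) q[k] += sigma * e[k];
    project_ball_buf(q, wq, alpha0, nbuf);
    for (size_t c = 0; c < nc; ++c)
      r[c] = rfac * (r[c] + sigma * (A.fwd(ubar, c) - f[c]));

    // primal updates with overrelaxation
    A.adj_accum(r, gu, buf);
    for (int b = 0; b < 3; ++b) gu += gradt(p[b], b);
    unew = u - tau * gu;
    symgrad_adj(q, w3);
    for (int b = 0; b < 3; ++b) vnew[b] = v[b] - tau * (w3[b] - p[b]);
    ubar = 2.0 * unew - u;
    for (int b = 0; b < 3; ++b) vbar[b] = 2.0 * vnew[b] - v[b];

    double rel = std::sqrt(norm2sq(unew - u)) /
      std::max(std::sqrt(norm2sq(unew)), 1e-30);
    std::swap(u, unew);
    for (int b = 0; b < 3; ++b) std::swap(v[b], vnew[b]);

    if (it % check_every == 0 || it == n_iter) {
      double en = 0.0;
      for (size_t c = 0; c < nc; ++c) en += norm2sq(A.fwd(u, c) - f[c]);
      en *= 0.5 * lambda;
      nbuf.zeros();
      for (int b = 0; b < 3; ++b) {
        gradd_into(u, b, gbuf);
        nbuf += square(abs(gbuf - v[b]));
      }
      en += alpha1 * accu(sqrt(nbuf));
      symgrad(v, e);
      nbuf.zeros();
      for (int k = 0; k < 6; ++k) nbuf += wq[k] * square(abs(e[k]));
      en += alpha0 * accu(sqrt(nbuf));
      tr_it.push_back(it);
      tr_en.push_back(en);
      tr_ch.push_back(rel);
      if (en > last_energy * (1.0 + 1e-8)) {
        if (++n_increase >= 5) diverged = true;
      } else n_increase = 0;
      last_energy = en;
      if (rel < tol) { iters_done = it; break; }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("u") = u,
    Rcpp::Named("trace") = Rcpp::DataFrame::create(
      Rcpp::Named("iteration") = tr_it,
      Rcpp::Named("energy") = tr_en,
      Rcpp::Named("rel_change") = tr_ch),
    Rcpp::Named("iterations") = iters_done,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("op_norm") = L,
    Rcpp::Named("step") = step);
}

// ---- ESPIRiT image-domain stage --------------------------------------------

// Given the row-space basis V (columns; length nk*nc each), transform each
// kernel to the image domain, accumulate the voxelwise nc x nc operator
// G(q) = sum_i w_i(q) w_i(q)^H, and return its leading eigenvector (power
// iteration) and eigenvalue per voxel.
// [[Rcpp::export]]
Rcpp::List cpp_espirit_maps(const arma::cx_mat& V, Rcpp::IntegerVector kernel,
                            Rcpp::IntegerVector grid, int nc, int n_power) {
  uword k1 = kernel[0], k2 = kernel[1], k3 = kernel[2];
  uword n1 = grid[0], n2 = grid[1], n3 = grid[2];
  uword nk = k1 * k2 * k3, nvox = n1 * n2 * n3;
  int h1 = n1 / 2, h2 = n2 / 2, h3 = n3 / 2;
  double scale = 1.0 / std::sqrt(static_cast<double>(nk));

  std::vector<cx_vec> G(nc * nc, cx_vec(nvox, fill::zeros));
  std::vector<cx_vec> w(nc);
  cx_cube pad(n1, n2, n3);
  for (uword i = 0; i < V.n_cols; ++i) {
    for (int c = 0; c < nc; ++c) {
      pad.zeros();
      const cx_double* src = V.colptr(i) + c * nk;
      for (uword s = 0; s < k3; ++s)
        for (uword j = 0; j < k2; ++j)
          for (uword r = 0; r < k1; ++r)
            pad(r, j, s) = src[r + j * k1 + s * k1 * k2];
      cx_cube g = circshift3(fft3_raw(pad, false), h1, h2, h3);
      w[c] = vectorise(g) * scale;
    }
    for (int a = 0; a < nc; ++a)
      for (int b = a; b < nc; ++b)
        G[a * nc + b] += conj(w[a]) % w[b];
  }
  for (int a = 0; a < nc; ++a)
    for (int b = 0; b < a; ++b)
      G[a * nc + b] = conj(G[b * nc + a]);

  // vectorized power iteration across voxels
  cx_mat m(nvox, nc);
  m.fill(cx_double(1.0 / std::sqrt(static_cast<double>(nc)), 0.0));
  cx_mat mn(nvox, nc);
  for (int it = 0; it < n_power; ++it) {
    mn.zeros();
    for (int a = 0; a < nc; ++a)
      for (int b = 0; b < nc; ++b)
        mn.col(a) += G[a * nc + b] % m.col(b);
    vec nrm = sqrt(sum(square(abs(mn)), 1));
    nrm.replace(0.0, 1.0);
    m = mn.each_col() / conv_to<cx_vec>::from(nrm);
  }
  mn.zeros();
  for (int a = 0; a < nc; ++a)
    for (int b = 0; b < nc; ++b)
      mn.col(a) += G[a * nc + b] % m.col(b);
  vec lam = real(sum(conj(m) % mn, 1));

  return Rcpp::List::create(Rcpp::Named("m") = m, Rcpp::Named("lambda") = lam);
}
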