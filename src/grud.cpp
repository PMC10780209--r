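// GRU-D-family recurrent cells for irregular clinical time series:
// forward pass and analytic backpropagation through time.
//
// One engine serves four variants, selected by flags:
//   cell   : 0 = gated (GRU-style), 1 = simple tanh RNN
//   decay  : 0/1  exponential decay gamma = exp(-relu(w*delta + b)) on the
//            stale last observation (per variable) and on the hidden state
//   mask_in: 0/1  observation mask fed to the gates through V projections
//   impute : 0 = none (input already complete, e.g. forward+mean filled)
//            1 = empirical  (GRU-D: decayed blend of last observation and a
//                frozen training mean; last obs seeded with that mean)
//            2 = head       (GRU-D++: decayed blend of last observation and
//                the hidden-state imputation estimate r_t = W_imp h + b_imp;
//                last obs seeded with the trainable x_init)
//            3 = trainable  (decayed blend with the trainable fallback
//                x_tilde; last obs seeded with x_init)
// The imputation head r_t is also trained through a masked reconstruction
// loss joined to the weighted classification BCE (lambda-weighted), making
// imputation and classification end-to-end in a single phase.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Flags {
  int cell, decay, mask_in, impute;
  bool gated() const { return cell == 0; }
  bool blend() const { return impute >= 1; }
  bool head_fallback() const { return impute == 2; }
  bool has_head(double lambda) const {
    return impute == 2 || (impute == 3 && lambda > 0);
  }
};

// Trainable quantities; (un)packed to/from a flat vector in a fixed layout
// that grud_param_layout() mirrors on the R side.
struct Params {
  mat Wz, Uz, Vz, Wr, Ur, Vr, Wc, Uc, Vc;
  vec bz, br, bc;
  vec w_gx, b_gx;
  mat W_gh; vec b_gh;
  vec x_tilde, x_init;
  mat W_imp; vec b_imp;
  vec w_out; double b_out; vec h0;

  Params(int D, int H) :
    Wz(H, D, fill::zeros), Uz(H, H, fill::zeros), Vz(H, D, fill::zeros),
    Wr(H, D, fill::zeros), Ur(H, H, fill::zeros), Vr(H, D, fill::zeros),
    Wc(H, D, fill::zeros), Uc(H, H, fill::zeros), Vc(H, D, fill::zeros),
    bz(H, fill::zeros), br(H, fill::zeros), bc(H, fill::zeros),
    w_gx(D, fill::zeros), b_gx(D, fill::zeros),
    W_gh(H, D, fill::zeros), b_gh(H, fill::zeros),
    x_tilde(D, fill::zeros), x_init(D, fill::zeros),
    W_imp(D, H, fill::zeros), b_imp(D, fill::zeros),
    w_out(H, fill::zeros), b_out(0.0), h0(H, fill::zeros) {}

  static int size(int D, int H) {
    return 3 * (H * D + H * H + H * D + H) + 2 * D + H * D + H +
           2 * D + D * H + D + H + 1 + H;
  }

  template <typename F> void walk(F f) {
    f(Wz); f(Uz); f(Vz); f(bz);
    f(Wr); f(Ur); f(Vr); f(br);
    f(Wc); f(Uc); f(Vc); f(bc);
    f(w_gx); f(b_gx); f(W_gh); f(b_gh);
    f(x_tilde); f(x_init); f(W_imp); f(b_imp);
    f(w_out);
  }

  void unpack(const vec& th, int D, int H) {
    uword pos = 0;
    auto rd = [&](auto& m) {
      uword n = m.n_elem;
      std::copy(th.memptr() + pos, th.memptr() + pos + n, m.memptr());
      pos += n;
    };
    walk(rd);
    b_out = th(pos); pos += 1;
    uword n = h0.n_elem;
    std::copy(th.memptr() + pos, th.memptr() + pos + n, h0.memptr());
    pos += n;
    if (pos != th.n_elem) Rcpp::stop("parameter vector has wrong length");
  }

  vec pack(int D, int H) {
    vec th(size(D, H));
    uword pos = 0;
    auto wr = [&](auto& m) {
      uword n = m.n_elem;
      std::copy(m.memptr(), m.memptr() + n, th.memptr() + pos);
      pos += n;
    };
    walk(wr);
    th(pos) = b_out; pos += 1;
    std::copy(h0.memptr(), h0.memptr() + h0.n_elem, th.memptr() + pos);
    return th;
  }
};

static inline vec relu(const vec& x) { return 0.5 * (x + abs(x)); }
static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct Trace {            // per-sequence forward intermediates
  mat XH, LO, GX, R;      // T x D
  mat HS, HHAT, Z, RG, C, GH;  // T x H
  vec P;                  // T
};

static void seq_forward(const mat& X, const mat& M, const mat& DL,
                        const Params& pr, const Flags& fl, const vec& xemp,
                        double lambda, Trace& tr) {
  const int T = X.n_rows, D = X.n_cols, H = pr.h0.n_elem;
  tr.XH.set_size(T, D); tr.LO.set_size(T, D); tr.GX.set_size(T, D);
  tr.HS.set_size(T, H); tr.HHAT.set_size(T, H); tr.GH.set_size(T, H);
  tr.P.set_size(T);
  bool head = fl.has_head(lambda);
  tr.R.set_size(head ? T : 0, D);
  if (fl.gated()) { tr.Z.set_size(T, H); tr.RG.set_size(T, H); tr.C.set_size(T, H); }

  vec lo = (fl.impute == 1) ? xemp : pr.x_init;
  vec h = pr.h0;
  for (int t = 0; t < T; ++t) {
    vec m = M.row(t).t(), d = DL.row(t).t();
    vec x = X.row(t).t();
    x.replace(datum::nan, 0.0);
    x %= m;  // observed values only; missing cells contribute 0

    vec gx(D, fill::ones), gh(H, fill::ones);
    if (fl.decay) {
      gx = exp(-relu(pr.w_gx % d + pr.b_gx));
      gh = exp(-relu(pr.W_gh * d + pr.b_gh));
    }
    tr.GX.row(t) = gx.t(); tr.GH.row(t) = gh.t();

    vec r;
    if (head) { r = pr.W_imp * h + pr.b_imp; tr.R.row(t) = r.t(); }

    vec xhat;
    if (!fl.blend()) {
      xhat = X.row(t).t();  // complete input required
    } else {
      vec fb = fl.head_fallback() ? r
             : (fl.impute == 3 ? pr.x_tilde : xemp);
      xhat = m % x + (1.0 - m) % (gx % lo + (1.0 - gx) % fb);
    }
    tr.LO.row(t) = lo.t(); tr.XH.row(t) = xhat.t();

    vec hhat = gh % h;
    tr.HHAT.row(t) = hhat.t();
    vec maskin = fl.mask_in ? m : vec(D, fill::zeros);
    if (fl.gated()) {
      vec z = sigm(pr.Wz * xhat + pr.Uz * hhat + pr.Vz * maskin + pr.bz);
      vec rg = sigm(pr.Wr * xhat + pr.Ur * hhat + pr.Vr * maskin + pr.br);
      vec c = tanh(pr.Wc * xhat + pr.Uc * (rg % hhat) + pr.Vc * maskin + pr.bc);
      h = (1.0 - z) % hhat + z % c;
      tr.Z.row(t) = z.t(); tr.RG.row(t) = rg.t(); tr.C.row(t) = c.t();
    } else {
      h = tanh(pr.Wz * xhat + pr.Uz * hhat + pr.Vz * maskin + pr.bz);
    }
    if (!h.is_finite())
      Rcpp::stop("non-finite hidden activation at timestep %d", t + 1);
    tr.HS.row(t) = h.t();
    tr.P(t) = 1.0 / (1.0 + exp(-(dot(pr.w_out, h) + pr.b_out)));

    if (fl.blend()) lo = m % x + (1.0 - m) % lo;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_seq_forward(const arma::mat& X, const arma::mat& M,
                           const arma::mat& DL, const arma::vec& theta,
                           int D, int H, Rcpp::List flags,
                           const arma::vec& xemp, double lambda) {
  Flags fl{flags["cell"], flags["decay"], flags["mask_in"], flags["impute"]};
  Params pr(D, H);
  pr.unpack(theta, D, H);
  Trace tr;
  seq_forward(X, M, DL, pr, fl, xemp, lambda, tr);
  return Rcpp::List::create(
    Rcpp::Named("p") = tr.P, Rcpp::Named("h") = tr.HS,
    Rcpp::Named("r") = tr.R, Rcpp::Named("xhat") = tr.XH);
}

// Backward pass for one sequence; accumulates into `gr`. Returns the
// per-patient loss (weighted BCE averaged over timesteps + lambda * masked
// reconstruction error).
static double seq_backward(const mat& X, const mat& M, const mat& DL,
                           const vec& Y, const Params& pr, Params& gr,
                           const Flags& fl, const vec& xemp,
                           double lambda, double w_pos) {
  const int T = X.n_rows, D = X.n_cols, H = pr.h0.n_elem;
  Trace tr;
  seq_forward(X, M, DL, pr, fl, xemp, lambda, tr);
  bool head = fl.has_head(lambda);

  mat Xz = X; Xz.replace(datum::nan, 0.0); Xz %= M;

  double Lc = 0.0;
  for (int t = 0; t < T; ++t) {
    double p = std::min(std::max(tr.P(t), 1e-12), 1.0 - 1e-12);
    double w = Y(t) > 0.5 ? w_pos : 1.0;
    Lc += -w * (Y(t) * std::log(p) + (1.0 - Y(t)) * std::log1p(-p));
  }
  Lc /= T;
  double msum = accu(M), Lr = 0.0;
  if (head && msum > 0)
    Lr = accu(M % square(Xz - tr.R)) / msum;
  double loss = Lc + lambda * Lr;

  vec dh(H, fill::zeros), dlo(D, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec m = M.row(t).t(), d = DL.row(t).t();
    vec hprev = (t == 0) ? pr.h0 : vec(tr.HS.row(t - 1).t());

    double w = Y(t) > 0.5 ? w_pos : 1.0;
    double dlogit = w * (tr.P(t) - Y(t)) / T;
    gr.w_out += dlogit * tr.HS.row(t).t();
    gr.b_out += dlogit;
    dh += dlogit * pr.w_out;

    vec hhat = tr.HHAT.row(t).t(), xhat = tr.XH.row(t).t();
    vec maskin = fl.mask_in ? m : vec(D, fill::zeros);
    vec dxhat(D, fill::zeros), dhhat(H, fill::zeros), dhprev(H, fill::zeros);

    if (fl.gated()) {
      vec z = tr.Z.row(t).t(), rg = tr.RG.row(t).t(), c = tr.C.row(t).t();
      vec dz = dh % (c - hhat);
      vec dc = dh % z;
      dhhat = dh % (1.0 - z);
      vec dcp = dc % (1.0 - square(c));
      gr.Wc += dcp * xhat.t(); gr.Uc += dcp * (rg % hhat).t();
      if (fl.mask_in) gr.Vc += dcp * maskin.t();
      gr.bc += dcp;
      dxhat += pr.Wc.t() * dcp;
      vec drgh = pr.Uc.t() * dcp;
      vec drg = drgh % hhat;
      dhhat += drgh % rg;
      vec dzp = dz % z % (1.0 - z);
      gr.Wz += dzp * xhat.t(); gr.Uz += dzp * hhat.t();
      if (fl.mask_in) gr.Vz += dzp * maskin.t();
      gr.bz += dzp;
      dxhat += pr.Wz.t() * dzp; dhhat += pr.Uz.t() * dzp;
      vec drp = drg % rg % (1.0 - rg);
      gr.Wr += drp * xhat.t(); gr.Ur += drp * hhat.t();
      if (fl.mask_in) gr.Vr += drp * maskin.t();
      gr.br += drp;
      dxhat += pr.Wr.t() * drp; dhhat += pr.Ur.t() * drp;
    } else {
      vec hcur = tr.HS.row(t).t();
      vec dpre = dh % (1.0 - square(hcur));
      gr.Wz += dpre * xhat.t(); gr.Uz += dpre * hhat.t();
      if (fl.mask_in) gr.Vz += dpre * maskin.t();
      gr.bz += dpre;
      dxhat += pr.Wz.t() * dpre; dhhat += pr.Uz.t() * dpre;
    }

    // hhat = gh % hprev
    vec gh = tr.GH.row(t).t();
    vec dgh = dhhat % hprev;
    dhprev += dhhat % gh;
    if (fl.decay) {
      vec sh = pr.W_gh * d + pr.b_gh;
      vec dsh = -dgh % gh % conv_to<vec>::from(sh > 0);
      gr.W_gh += dsh * d.t(); gr.b_gh += dsh;
    }

    // dr collects head gradient from both the blend and the reconstruction
    vec dr(D, fill::zeros);
    if (head && msum > 0)
      dr += lambda * 2.0 * (m % (tr.R.row(t).t() - Xz.row(t).t())) / msum;

    if (fl.blend()) {
      vec gx = tr.GX.row(t).t(), lo = tr.LO.row(t).t();
      vec fb = fl.head_fallback() ? vec(tr.R.row(t).t())
             : (fl.impute == 3 ? pr.x_tilde : xemp);
      vec dmiss = dxhat % (1.0 - m);
      vec dgx = dmiss % (lo - fb);
      vec dfb = dmiss % (1.0 - gx);
      if (fl.decay) {
        vec sx = pr.w_gx % d + pr.b_gx;
        vec dsx = -dgx % gx % conv_to<vec>::from(sx > 0);
        gr.w_gx += dsx % d; gr.b_gx += dsx;
      }
      if (fl.head_fallback()) dr += dfb;
      else if (fl.impute == 3) gr.x_tilde += dfb;
      // lo_{t+1} = m x + (1-m) lo_t : chain to earlier steps
      dlo = dlo % (1.0 - m) + dmiss % gx;
    }
    if (head) {
      gr.W_imp += dr * hprev.t();
      gr.b_imp += dr;
      dhprev += pr.W_imp.t() * dr;
    }
    dh = dhprev;
  }
  if (fl.blend() && fl.impute != 1) gr.x_init += dlo;
  gr.h0 += dh;
  return loss;
}

// [[Rcpp::export]]
Rcpp::List cpp_batch_loss_grad(Rcpp::List xs, Rcpp::List ms, Rcpp::List dls,
                               Rcpp::List ys, const arma::vec& theta,
                               int D, int H, Rcpp::List flags,
                               const arma::vec& xemp, double lambda,
                               double w_pos) {
  Flags fl{flags["cell"], flags["decay"], flags["mask_in"], flags["impute"]};
  Params pr(D, H), gr(D, H);
  pr.unpack(theta, D, H);
  const int N = xs.size();
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    mat X = Rcpp::as<mat>(xs[i]), M = Rcpp::as<mat>(ms[i]),
        DL = Rcpp::as<mat>(dls[i]);
    vec Y = Rcpp::as<vec>(ys[i]);
    loss += seq_backward(X, M, DL, Y, pr, gr, fl, xemp, lambda, w_pos);
  }
  loss /= N;
  vec grad = gr.pack(D, H) / N;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
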