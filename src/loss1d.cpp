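// Fast path for the 1-D teacher-forced rollout loss and its exact
// reverse-mode gradient.  Mirrors the reference R implementation
// (loss_and_grad, rhs_forward, rhs_backward) operation for operation; the
// test suite asserts agreement to near machine precision.
//
// Fields are stored transposed (batch x space) so the spatial stencil
// sweeps contiguous column blocks, and all step-level buffers are
// allocated once and reused across micro-steps.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

namespace {

// mirror pad along columns (cell-centered even reflection)
void mirror_pad(const mat& U, int h, mat& Up) {
  const int n = U.n_cols;
  Up.set_size(U.n_rows, n + 2 * h);
  Up.cols(h, h + n - 1) = U;
  for (int j = 0; j < h; ++j) {
    Up.col(h - 1 - j) = U.col(j);
    Up.col(h + n + j) = U.col(n - 1 - j);
  }
}

// correlation against a padded field: out(., i) = sum_k q[k] Up(., i + k).
// Column-wise sweep keeps the 19-column window in L1 cache.
void conv_from_pad(const mat& Up, const vec& q, int n, mat& out) {
  const int B = Up.n_rows, N = q.n_elem;
  out.set_size(B, n);
  for (int i = 0; i < n; ++i) {
    double* o = out.colptr(i);
    std::fill(o, o + B, 0.0);
    for (int k = 0; k < N; ++k) {
      const double qk = q[k];
      if (qk == 0.0) continue;
      const double* up = Up.colptr(i + k);
      for (int b = 0; b < B; ++b) o[b] += qk * up[b];
    }
  }
}

// adjoint of the mirror-padded correlation w.r.t. the input field
void conv_adj(const mat& G, const vec& q, int n, mat& Gp, mat& out) {
  const int N = q.n_elem, h = (N - 1) / 2, B = G.n_rows;
  Gp.zeros(B, n + 2 * h);
  for (int i = 0; i < n; ++i) {
    const double* g = G.colptr(i);
    for (int k = 0; k < N; ++k) {
      const double qk = q[k];
      if (qk == 0.0) continue;
      double* gp = Gp.colptr(i + k);
      for (int b = 0; b < B; ++b) gp[b] += qk * g[b];
    }
  }
  out = Gp.cols(h, h + n - 1);
  for (int j = 0; j < h; ++j) {
    out.col(j)         += Gp.col(h - 1 - j);
    out.col(n - 1 - j) += Gp.col(h + n + j);
  }
}

// gradient of sum(G % conv) w.r.t. kernel entries, from the padded field
void conv_kernel_grad(const mat& G, const mat& Up, int n, int N, vec& gq) {
  const int B = G.n_rows;
  for (int i = 0; i < n; ++i) {
    const double* g = G.colptr(i);
    for (int k = 0; k < N; ++k) {
      const double* up = Up.colptr(i + k);
      double s = 0.0;
      for (int b = 0; b < B; ++b) s += g[b] * up[b];
      gq[k] += s;
    }
  }
}

struct NetSpec {
  int k = 0;
  std::vector<int> kind;        // 0 multiply, 1 divide
  std::vector<mat> W;           // 2 x (nch + i - 1)
  std::vector<vec> b;
  std::vector<umat> mW;         // trainable-entry masks
  std::vector<uvec> mb;
  vec Wout; double bout = 0.0;
  uvec mWout; int mbout = 1;
  uvec chan;                    // global channel index per library slot
};

NetSpec read_net(const List& net) {
  NetSpec s;
  s.kind = as<std::vector<int>>(net["kind"]);
  s.k = s.kind.size();
  List Wl = net["W"], bl = net["b"];
  List mWl = net["mW"], mbl = net["mb"];
  for (int i = 0; i < s.k; ++i) {
    s.W.push_back(as<mat>(Wl[i]));
    s.b.push_back(as<vec>(bl[i]));
    s.mW.push_back(as<umat>(mWl[i]));
    s.mb.push_back(as<uvec>(mbl[i]));
  }
  s.Wout = as<vec>(net["Wout"]);
  s.bout = as<double>(net["bout"]);
  s.mWout = as<uvec>(net["mWout"]);
  s.mbout = as<int>(net["mbout"]);
  s.chan = as<uvec>(net["chan"]);
  return s;
}

struct NetGrads {
  std::vector<mat> gW;
  std::vector<vec> gb;
  vec gWout; double gbout = 0.0;
  void init(const NetSpec& s) {
    for (int i = 0; i < s.k; ++i) {
      gW.push_back(mat(2, s.W[i].n_cols, fill::zeros));
      gb.push_back(vec(2, fill::zeros));
    }
    gWout = vec(s.Wout.n_elem, fill::zeros);
    gbout = 0.0;
  }
};

// per-step working storage for one network (buffers reused across steps);
// the library prefix is referenced from the shared channel array, only the
// unit outputs are owned.
struct NetCache {
  std::vector<const mat*> Lp;
  std::vector<mat> f, eta, xi, xs, gL;
  double penalty = 0.0;
  void init(const NetSpec& s) {
    Lp.resize(s.chan.n_elem + s.k, nullptr);
    f.resize(s.k);
    eta.resize(s.k); xi.resize(s.k); xs.resize(s.k);
    gL.resize(s.chan.n_elem + s.k);
  }
};

void net_forward(const NetSpec& s, const std::vector<mat>& chan,
                 double eps_div, double pen_tau, NetCache& cc, mat& out) {
  const int nch = s.chan.n_elem;
  const int B = chan[s.chan[0]].n_rows, n = chan[s.chan[0]].n_cols;
  cc.penalty = 0.0;
  for (int c = 0; c < nch; ++c) cc.Lp[c] = &chan[s.chan[c]];
  for (int i = 0; i < s.k; ++i) cc.Lp[nch + i] = &cc.f[i];
  for (int i = 0; i < s.k; ++i) {
    mat& eta = cc.eta[i]; mat& xi = cc.xi[i];
    eta.set_size(B, n); eta.fill(s.b[i][0]);
    xi.set_size(B, n);  xi.fill(s.b[i][1]);
    for (unsigned c = 0; c < s.W[i].n_cols; ++c) {
      if (s.W[i](0, c) != 0.0) eta += s.W[i](0, c) * (*cc.Lp[c]);
      if (s.W[i](1, c) != 0.0) xi  += s.W[i](1, c) * (*cc.Lp[c]);
    }
    mat& f = cc.f[i];
    if (s.kind[i] == 0) {
      f = eta % xi;
    } else {
      mat& xs = cc.xs[i];
      xs = abs(xi);
      double pshort = 0.0;
      for (unsigned j = 0; j < xs.n_elem; ++j) {
        if (xs[j] < pen_tau) pshort += pen_tau - xs[j];
        if (xs[j] < eps_div) xs[j] = eps_div;
        if (xi[j] < 0) xs[j] = -xs[j];
      }
      cc.penalty += pshort / (pen_tau * double(n) * B);
      f = eta / xs;
    }
  }
  out.set_size(B, n); out.fill(s.bout);
  for (unsigned c = 0; c < s.Wout.n_elem; ++c)
    if (s.Wout[c] != 0.0) out += s.Wout[c] * (*cc.Lp[c]);
}

void net_backward(const NetSpec& s, NetCache& cc, const mat& gout,
                  double eps_div, double pen_tau, double pen_w,
                  NetGrads& gg, std::vector<mat>& gchan_global) {
  const int nch = s.chan.n_elem;
  const int B = gout.n_rows, n = gout.n_cols;
  for (auto& g : cc.gL) g.zeros(B, n);
  for (unsigned c = 0; c < s.Wout.n_elem; ++c) {
    if (s.mWout[c]) gg.gWout[c] += accu(gout % (*cc.Lp[c]));
    if (s.Wout[c] != 0.0) cc.gL[c] += s.Wout[c] * gout;
  }
  if (s.mbout) gg.gbout += accu(gout);
  const double npts = double(n) * B;
  mat geta, gxi;
  for (int i = s.k - 1; i >= 0; --i) {
    const mat& gf = cc.gL[nch + i];
    (void)eps_div;
    if (s.kind[i] == 0) {
      geta = gf % cc.xi[i];
      gxi  = gf % cc.eta[i];
    } else {
      geta = gf / cc.xs[i];
      gxi  = -(gf % cc.eta[i]) / (cc.xs[i] % cc.xs[i]);
      for (unsigned j = 0; j < gxi.n_elem; ++j) {
        double axi = std::fabs(cc.xi[i][j]);
        if (axi < eps_div) gxi[j] = 0.0;
        if (pen_w > 0.0 && axi < pen_tau)
          gxi[j] -= pen_w * (cc.xi[i][j] >= 0 ? 1.0 : -1.0) /
            (pen_tau * npts);
      }
    }
    for (unsigned c = 0; c < s.W[i].n_cols; ++c) {
      if (s.mW[i](0, c)) gg.gW[i](0, c) += accu(geta % (*cc.Lp[c]));
      if (s.mW[i](1, c)) gg.gW[i](1, c) += accu(gxi % (*cc.Lp[c]));
      if (s.W[i](0, c) != 0.0) cc.gL[c] += s.W[i](0, c) * geta;
      if (s.W[i](1, c) != 0.0) cc.gL[c] += s.W[i](1, c) * gxi;
    }
    if (s.mb[i][0]) gg.gb[i][0] += accu(geta);
    if (s.mb[i][1]) gg.gb[i][1] += accu(gxi);
  }
  for (int c = 0; c < nch; ++c) gchan_global[s.chan[c]] += cc.gL[c];
}

void soft_clip_inplace(mat& x, double c, double B) {
  for (unsigned j = 0; j < x.n_elem; ++j) {
    double a = std::fabs(x[j]);
    if (a > c) {
      double s = x[j] >= 0 ? 1.0 : -1.0;
      x[j] = s * (c + (B - c) * std::tanh((a - c) / (B - c)));
    }
  }
}

struct Plan {
  std::vector<vec> q;
  std::vector<double> dscl;     // dx^order per filter
  std::vector<bool> train;
  imat chan;                    // rows: (type, field, filt)
  NetSpec n1, n2;
  double eta = 0.0; bool has_eta = false;
  double dx = 0.0;
  int h = 0;                    // kernel half width
};

// all reusable step-level buffers
struct Work {
  mat Upu, Upv;                 // padded raw fields
  mat d0u, d0v, powbase, powval;
  std::vector<mat> chan, gchan, gderiv;
  NetCache c1, c2;
  mat F1, F2, zu, zv, geta_buf;
  mat Gp, gtmp, gstate;
  double penalty = 0.0;
};

void rhs_forward(const Plan& P, const mat& U, const mat& V, Work& w,
                 double eps_div, double pen_tau) {
  const int n = U.n_cols, B = U.n_rows;
  mirror_pad(U, P.h, w.Upu);
  mirror_pad(V, P.h, w.Upv);
  conv_from_pad(w.Upu, P.q[0], n, w.d0u); w.d0u /= P.dscl[0];
  conv_from_pad(w.Upv, P.q[0], n, w.d0v); w.d0v /= P.dscl[0];
  double alpha = 1.5 + 0.5 * std::sin(P.eta);
  for (unsigned c = 0; c < w.chan.size(); ++c) {
    int type = P.chan(c, 0), field = P.chan(c, 1), filt = P.chan(c, 2);
    const mat& Up = field == 0 ? w.Upu : w.Upv;
    const mat& base = field == 0 ? w.d0u : w.d0v;
    switch (type) {
    case 0:
      if (filt == 0) w.chan[c] = base;
      else {
        conv_from_pad(Up, P.q[filt], n, w.chan[c]);
        w.chan[c] /= P.dscl[filt];
      }
      break;
    case 1: w.chan[c] = base % base; break;
    case 2: {
      w.powbase = base;
      for (unsigned j = 0; j < w.powbase.n_elem; ++j)
        if (w.powbase[j] < 0) w.powbase[j] = 0;
      w.powval = pow(w.powbase, alpha);
      w.chan[c] = w.powval;
      break;
    }
    case 3: {
      vec I = P.dx * sum(base, 1);
      w.chan[c].set_size(B, n);
      w.chan[c].each_col() = I;
      break;
    }
    }
  }
  net_forward(P.n1, w.chan, eps_div, pen_tau, w.c1, w.F1);
  net_forward(P.n2, w.chan, eps_div, pen_tau, w.c2, w.F2);
  w.penalty = w.c1.penalty + w.c2.penalty;
}

struct Accum {
  std::vector<vec> gq;
  NetGrads g1, g2;
  double geta = 0.0;
};

void rhs_backward(const Plan& P, const mat& U, const mat& V, Work& w,
                  const mat& gF1, const mat& gF2, Accum& acc,
                  double eps_div, double pen_tau, double pen_w,
                  mat& gU, mat& gV) {
  const int n = U.n_cols, B = U.n_rows;
  const int nf = P.q.size();
  for (auto& g : w.gchan) g.zeros(B, n);
  net_backward(P.n1, w.c1, gF1, eps_div, pen_tau, pen_w, acc.g1, w.gchan);
  net_backward(P.n2, w.c2, gF2, eps_div, pen_tau, pen_w, acc.g2, w.gchan);

  for (auto& g : w.gderiv) g.reset();
  auto addd = [&](int filt, int field, const mat& g) {
    int key = filt + nf * field;
    if (w.gderiv[key].n_elem == 0) w.gderiv[key] = g;
    else w.gderiv[key] += g;
  };
  double alpha = 1.5 + 0.5 * std::sin(P.eta);
  for (unsigned c = 0; c < w.gchan.size(); ++c) {
    int type = P.chan(c, 0), field = P.chan(c, 1), filt = P.chan(c, 2);
    const mat& base = field == 0 ? w.d0u : w.d0v;
    const mat& gc = w.gchan[c];
    switch (type) {
    case 0: addd(filt, field, gc); break;
    case 1: addd(0, field, 2.0 * (base % gc)); break;
    case 2: {
      // d/dbase base^alpha = alpha base^(alpha-1) = alpha powval / base
      w.gtmp.set_size(gc.n_rows, gc.n_cols);
      double sacc = 0.0;
      for (unsigned j = 0; j < w.gtmp.n_elem; ++j) {
        if (w.powbase[j] > 0 && base[j] > 0) {
          w.gtmp[j] = gc[j] * alpha * w.powval[j] / w.powbase[j];
          if (P.has_eta)
            sacc += gc[j] * w.powval[j] * std::log(w.powbase[j]);
        } else w.gtmp[j] = 0.0;
      }
      addd(0, field, w.gtmp);
      if (P.has_eta) acc.geta += 0.5 * std::cos(P.eta) * sacc;
      break;
    }
    case 3: {
      vec gI = P.dx * sum(gc, 1);
      w.gtmp.set_size(B, n);
      w.gtmp.each_col() = gI;
      addd(0, field, w.gtmp);
      break;
    }
    }
  }
  gU.zeros(B, n); gV.zeros(B, n);
  for (int filt = 0; filt < nf; ++filt) {
    for (int field = 0; field < 2; ++field) {
      int key = filt + nf * field;
      if (w.gderiv[key].n_elem == 0) continue;
      w.gderiv[key] /= P.dscl[filt];
      conv_adj(w.gderiv[key], P.q[filt], n, w.Gp, w.gstate);
      if (P.train[filt])
        conv_kernel_grad(w.gderiv[key], field == 0 ? w.Upu : w.Upv, n,
                         P.q[filt].n_elem, acc.gq[filt]);
      if (field == 0) gU += w.gstate; else gV += w.gstate;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".fp_loss1d_teacher")]]
List fp_loss1d_teacher(const arma::mat& u0, const arma::mat& v0,
                       const arma::mat& utgt, const arma::mat& vtgt,
                       List kernels, NumericVector dscales,
                       LogicalVector trainable,
                       IntegerMatrix chan_tab, List net1, List net2,
                       double eta, bool has_eta,
                       int m, double delta, double scale, double wspace,
                       double clip_c, double clip_B, double eps_div,
                       double pen_tau, double pen_w_total, bool want_grad) {
  Plan P;
  for (int i = 0; i < kernels.size(); ++i) {
    P.q.push_back(as<vec>(kernels[i]));
    P.dscl.push_back(dscales[i]);
    P.train.push_back(trainable[i]);
  }
  P.chan = as<imat>(chan_tab);
  P.n1 = read_net(net1); P.n2 = read_net(net2);
  P.eta = eta; P.has_eta = has_eta;
  P.dx = dscales[1];
  P.h = (P.q[0].n_elem - 1) / 2;

  Work w;
  w.chan.resize(P.chan.n_rows);
  w.gchan.resize(P.chan.n_rows);
  w.gderiv.resize(2 * P.q.size());
  w.c1.init(P.n1); w.c2.init(P.n2);

  std::vector<mat> su(m), sv(m);
  mat u = u0.t(), v = v0.t();
  const mat ut = utgt.t(), vt = vtgt.t();
  double penalty = 0.0;
  bool blown = false;
  for (int s = 0; s < m; ++s) {
    su[s] = u; sv[s] = v;
    rhs_forward(P, u, v, w, eps_div, pen_tau);
    penalty += w.penalty / m;
    u += delta * w.F1;
    v += delta * w.F2;
    soft_clip_inplace(u, clip_c, clip_B);
    soft_clip_inplace(v, clip_c, clip_B);
    if (!u.is_finite() || !v.is_finite()) { blown = true; break; }
  }
  if (blown)
    return List::create(_["Ldata"] = 1e10, _["penalty"] = 0.0,
                        _["blown"] = true);
  mat ru = u - ut, rv = v - vt;
  double Ldata = scale * wspace * (accu(ru % ru) + accu(rv % rv));
  List out = List::create(_["Ldata"] = Ldata, _["penalty"] = penalty,
                          _["blown"] = false);
  if (!want_grad) return out;

  Accum acc;
  for (auto& q : P.q) acc.gq.push_back(vec(q.n_elem, fill::zeros));
  acc.g1.init(P.n1); acc.g2.init(P.n2);
  double pen_w = pen_w_total / m;
  mat au = 2.0 * scale * wspace * ru;
  mat av = 2.0 * scale * wspace * rv;
  mat gU, gV, zu, zv;
  for (int s = m - 1; s >= 0; --s) {
    rhs_forward(P, su[s], sv[s], w, eps_div, pen_tau);
    zu = su[s] + delta * w.F1;
    zv = sv[s] + delta * w.F2;
    // chain through the soft clip (derivative 1 inside |x| <= c)
    for (unsigned j = 0; j < zu.n_elem; ++j) {
      double a = std::fabs(zu[j]);
      if (a > clip_c) {
        double t = std::cosh((a - clip_c) / (clip_B - clip_c));
        au[j] /= t * t;
      }
      a = std::fabs(zv[j]);
      if (a > clip_c) {
        double t = std::cosh((a - clip_c) / (clip_B - clip_c));
        av[j] /= t * t;
      }
    }
    zu = delta * au;   // gF1
    zv = delta * av;   // gF2
    rhs_backward(P, su[s], sv[s], w, zu, zv, acc, eps_div, pen_tau, pen_w,
                 gU, gV);
    au += gU; av += gV;
  }
  List gq(P.q.size());
  for (unsigned i = 0; i < P.q.size(); ++i) gq[i] = wrap(acc.gq[i]);
  List g1W(P.n1.k), g1b(P.n1.k), g2W(P.n2.k), g2b(P.n2.k);
  for (int i = 0; i < P.n1.k; ++i) {
    g1W[i] = wrap(acc.g1.gW[i]); g1b[i] = wrap(acc.g1.gb[i]);
  }
  for (int i = 0; i < P.n2.k; ++i) {
    g2W[i] = wrap(acc.g2.gW[i]); g2b[i] = wrap(acc.g2.gb[i]);
  }
  out["gq"] = gq;
  out["g1"] = List::create(_["W"] = g1W, _["b"] = g1b,
                           _["Wout"] = wrap(acc.g1.gWout),
                           _["bout"] = acc.g1.gbout);
  out["g2"] = List::create(_["W"] = g2W, _["b"] = g2b,
                           _["Wout"] = wrap(acc.g2.gWout),
                           _["bout"] = acc.g2.gbout);
  out["geta"] = acc.geta;
  return out;
}
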