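#include <Rcpp.h>
using namespace Rcpp;

// Union-find over sensor-time points that survive the forming criterion.
// Step 1 keeps, per sensor, only supra-threshold runs of >= min_run
// consecutive samples. Step 2 links surviving points that share a sensor
// and are adjacent in time, or share a sample and are neighboring sensors.

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// fmat: sensors x time F values; adj: list of 1-based neighbor index vectors
// Returns labels (sensors x time, 0 = not in a cluster) and per-cluster
// mass, ordered by descending mass with ties broken by earliest time then
// lowest sensor index.
// [[Rcpp::export]]
List form_clusters_cpp(NumericMatrix fmat, double thresh, int min_run,
                       List adj) {
  const int ns = fmat.nrow(), nt = fmat.ncol();
  std::vector<char> keep((size_t)ns * nt, 0);

  // duration rule, per sensor
  for (int s = 0; s < ns; ++s) {
    int run = 0;
    for (int t = 0; t <= nt; ++t) {
      bool supra = (t < nt) && (fmat(s, t) > thresh);
      if (supra) {
        ++run;
      } else {
        if (run >= min_run)
          for (int u = t - run; u < t; ++u) keep[(size_t)s + (size_t)u * ns] = 1;
        run = 0;
      }
    }
  }

  // union-find over surviving points
  std::vector<int> parent((size_t)ns * nt);
  for (size_t i = 0; i < parent.size(); ++i) parent[i] = (int)i;
  for (int t = 0; t < nt; ++t) {
    for (int s = 0; s < ns; ++s) {
      size_t id = (size_t)s + (size_t)t * ns;
      if (!keep[id]) continue;
      if (t + 1 < nt && keep[id + ns]) uf_union(parent, (int)id, (int)(id + ns));
      IntegerVector nb = adj[s];
      for (int k = 0; k < nb.size(); ++k) {
        int s2 = nb[k] - 1;
        if (s2 > s) {
          size_t id2 = (size_t)s2 + (size_t)t * ns;
          if (keep[id2]) uf_union(parent, (int)id, (int)id2);
        }
      }
    }
  }

  // collect components
  std::map<int, int> root2lab;
  std::vector<double> mass;
  std::vector<int> first_t, min_s, npts;
  IntegerMatrix labels(ns, nt);
  for (int t = 0; t < nt; ++t) {
    for (int s = 0; s < ns; ++s) {
      size_t id = (size_t)s + (size_t)t * ns;
      if (!keep[id]) continue;
      int root = uf_find(parent, (int)id);
      auto it = root2lab.find(root);
      int lab;
      if (it == root2lab.end()) {
        lab = (int)mass.size();
        root2lab[root] = lab;
        mass.push_back(0.0);
        first_t.push_back(t);
        min_s.push_back(s);
        npts.push_back(0);
      } else {
        lab = it->second;
      }
      mass[lab] += fmat(s, t);
      if (t < first_t[lab]) first_t[lab] = t;
      if (s < min_s[lab]) min_s[lab] = s;
      npts[lab] += 1;
      labels(s, t) = lab + 1; // provisional, re-ranked below
    }
  }

  // order: descending mass, ties by earliest onset then lowest sensor
  const int nc = (int)mass.size();
  std::vector<int> ord(nc);
  for (int i = 0; i < nc; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (mass[a] != mass[b]) return mass[a] > mass[b];
    if (first_t[a] != first_t[b]) return first_t[a] < first_t[b];
    return min_s[a] < min_s[b];
  });
  std::vector<int> rank(nc);
  for (int i = 0; i < nc; ++i) rank[ord[i]] = i + 1;
  for (int t = 0; t < nt; ++t)
    for (int s = 0; s < ns; ++s)
      if (labels(s, t) > 0) labels(s, t) = rank[labels(s, t) - 1];

  NumericVector out_mass(nc);
  IntegerVector out_npts(nc);
  for (int i = 0; i < nc; ++i) {
    out_mass[i] = mass[ord[i]];
    out_npts[i] = npts[ord[i]];
  }
  return List::create(_["labels"] = labels, _["mass"] = out_mass,
                      _["n_points"] = out_npts);
}

// Maximum cluster mass only (the permutation-null statistic); avoids
// building label matrices inside the Monte-Carlo loop.
// [[Rcpp::export]]
double max_cluster_mass_cpp(NumericMatrix fmat, double thresh, int min_run,
                            List adj) {
  List res = form_clusters_cpp(fmat, thresh, min_run, adj);
  NumericVector m = res["mass"];
  return m.size() ? (double)m[0] : 0.0;
}
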