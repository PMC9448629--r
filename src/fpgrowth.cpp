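// Local FP-growth miner used by the partitioned (shard-and-merge) pipeline.
// Items arrive as integer codes equal to their global F-list rank (1 = most
// frequent); transactions are pre-filtered to F-list items and sorted by
// ascending code. Itemsets are emitted as "c1|c2|..." keys over ascending
// codes so that per-shard results can be summed by key and decoded once,
// after global thresholding.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct FPTree {
  std::vector<int> item, parent, count, next_node;
  std::vector<std::unordered_map<int, int>> kids;
  std::vector<int> header;      // per code: head of node chain, -1 if absent
  std::vector<long long> item_count;
  std::vector<int> present;     // codes present, ascending

  explicit FPTree(int n_items)
      : header(n_items + 1, -1), item_count(n_items + 1, 0) {
    item.push_back(0);
    parent.push_back(-1);
    count.push_back(0);
    next_node.push_back(-1);
    kids.emplace_back();
  }

  void insert(const std::vector<int>& codes, int w) {
    int cur = 0;
    for (int c : codes) {
      int nid;
      auto it = kids[cur].find(c);
      if (it == kids[cur].end()) {
        nid = static_cast<int>(item.size());
        item.push_back(c);
        parent.push_back(cur);
        count.push_back(w);
        next_node.push_back(header[c]);
        header[c] = nid;
        kids.emplace_back();
        kids[cur].emplace(c, nid);
      } else {
        nid = it->second;
        count[nid] += w;
      }
      item_count[c] += w;
      cur = nid;
    }
  }

  void finalize_present() {
    for (int c = 1; c < static_cast<int>(header.size()); ++c)
      if (header[c] >= 0) present.push_back(c);
  }

  bool single_path() const {
    for (const auto& m : kids)
      if (m.size() > 1) return false;
    return true;
  }
};

struct Miner {
  std::vector<std::string> keys;
  std::vector<int> sups;
  int min_support;
  std::vector<int> suffix;  // codes in strictly descending order

  void emit(const std::vector<int>& subset_asc, int support) {
    // subset_asc ascending, suffix descending; merge to one ascending key
    std::string key;
    key.reserve(8 * (subset_asc.size() + suffix.size()));
    for (int c : subset_asc) {
      if (!key.empty()) key.push_back('|');
      key += std::to_string(c);
    }
    for (auto it = suffix.rbegin(); it != suffix.rend(); ++it) {
      if (!key.empty()) key.push_back('|');
      key += std::to_string(*it);
    }
    keys.push_back(std::move(key));
    sups.push_back(support);
  }

  // conditional database: prefix paths (ascending codes) with weights
  void mine(const std::vector<std::vector<int>>& db,
            const std::vector<int>& wts, int n_items,
            const std::vector<char>* allowed) {
    FPTree tree(n_items);
    {
      // filter to locally frequent items before insertion
      std::vector<long long> tally(n_items + 1, 0);
      for (size_t i = 0; i < db.size(); ++i)
        for (int c : db[i]) tally[c] += wts[i];
      std::vector<int> buf;
      for (size_t i = 0; i < db.size(); ++i) {
        buf.clear();
        for (int c : db[i])
          if (tally[c] >= min_support) buf.push_back(c);
        if (!buf.empty()) tree.insert(buf, wts[i]);
      }
    }
    tree.finalize_present();
    if (tree.present.empty()) return;

    if (tree.single_path() && !allowed) {
      // path items in ascending code = root-to-leaf order
      std::vector<int> pitems, pcounts;
      int cur = 0;
      while (!tree.kids[cur].empty()) {
        int nid = tree.kids[cur].begin()->second;
        pitems.push_back(tree.item[nid]);
        pcounts.push_back(tree.count[nid]);
        cur = nid;
      }
      int d = static_cast<int>(pitems.size());
      if (d <= 24) {
        std::vector<int> subset;
        for (unsigned mask = 1; mask < (1u << d); ++mask) {
          int deepest = 31 - __builtin_clz(mask);
          if (pcounts[deepest] < min_support) continue;
          subset.clear();
          for (int j = 0; j <= deepest; ++j)
            if (mask & (1u << j)) subset.push_back(pitems[j]);
          emit(subset, pcounts[deepest]);
        }
        return;
      }
      // unusually long path: fall through to the generic recursion
    }

    std::vector<int> single(1);
    for (auto it = tree.present.rbegin(); it != tree.present.rend(); ++it) {
      int c = *it;
      if (tree.item_count[c] < min_support) continue;
      if (allowed && !(*allowed)[c]) continue;
      single[0] = c;
      emit(single, static_cast<int>(tree.item_count[c]));
      // conditional pattern base of c
      std::vector<std::vector<int>> cdb;
      std::vector<int> cwt;
      for (int nid = tree.header[c]; nid >= 0; nid = tree.next_node[nid]) {
        std::vector<int> path;
        for (int p = tree.parent[nid]; p > 0; p = tree.parent[p])
          path.push_back(tree.item[p]);
        if (path.empty()) continue;
        std::reverse(path.begin(), path.end());
        cdb.push_back(std::move(path));
        cwt.push_back(tree.count[nid]);
      }
      if (!cdb.empty()) {
        suffix.push_back(c);
        mine(cdb, cwt, c - 1, nullptr);
        suffix.pop_back();
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_fpgrowth(List trans, int n_items, int min_support,
                  IntegerVector allowed_codes, bool use_filter) {
  std::vector<std::vector<int>> db;
  db.reserve(trans.size());
  std::vector<int> wts;
  wts.reserve(trans.size());
  for (R_xlen_t i = 0; i < trans.size(); ++i) {
    IntegerVector t = trans[i];
    if (t.size() == 0) continue;
    db.emplace_back(t.begin(), t.end());
    wts.push_back(1);
  }
  Miner m;
  m.min_support = min_support;
  std::vector<char> allowed;
  const std::vector<char>* allowed_ptr = nullptr;
  if (use_filter) {
    allowed.assign(n_items + 1, 0);
    for (int c : allowed_codes)
      if (c >= 1 && c <= n_items) allowed[c] = 1;
    allowed_ptr = &allowed;
  }
  if (!db.empty()) m.mine(db, wts, n_items, allowed_ptr);
  return List::create(_["key"] = wrap(m.keys), _["count"] = wrap(m.sups));
}
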