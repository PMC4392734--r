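{
  "title": "linkernet JSON report",
  "type": "object",
  "required": ["package", "version", "config", "geneList", "networks"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "config": {
      "type": "object",
      "required": ["maxDepth", "minListGenes", "nSim", "seed",
                   "universeSize", "listSize"]
    },
    "geneList": {"type": "array"},
    "networks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rank", "startGene", "depth", "nodes", "edges", "stats"],
        "properties": {
          "nodes": {
            "type": "array",
            "items": {"type": "object",
                      "required": ["gene", "isList", "isLinker"]}
          },
          "edges": {
            "type": "array",
            "items": {"type": "object",
                      "required": ["geneA", "geneB", "citations"]}
          },
          "stats": {
            "type": "object",
            "required": ["score", "scorePvalue", "nSim",
                         "neighbourhoodSize", "listOverlap", "listPvalue"]
          }
        }
      }
    }
  }
}
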