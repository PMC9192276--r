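{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ctsurf pipeline run report",
  "type": "object",
  "required": ["package", "version", "seed", "parameters", "stages"],
  "properties": {
    "package": {"const": "ctsurf"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "parameters": {"type": "object"},
    "elapsedSeconds": {"type": "number"},
    "stages": {
      "type": "object",
      "required": ["classify", "reconstruct"],
      "properties": {
        "phantom": {
          "type": "object",
          "properties": {
            "description": {"type": "string"},
            "analyticVolume": {"type": "number"},
            "analyticArea": {"type": "number"},
            "approximateTruth": {"type": "boolean"}
          }
        },
        "classify": {
          "type": "object",
          "required": ["dims", "nInside", "nOn", "nOutside"]
        },
        "reconstruct": {"$ref": "#/$defs/meshStats"},
        "simplify": {"$ref": "#/$defs/meshStats"}
      }
    }
  },
  "$defs": {
    "meshStats": {
      "type": "object",
      "required": ["nVertices", "nEdges", "nFaces", "eulerCharacteristic",
                   "watertight", "surfaceArea", "enclosedVolume"],
      "properties": {
        "nVertices": {"type": "integer"},
        "nEdges": {"type": "integer"},
        "nFaces": {"type": "integer"},
        "eulerCharacteristic": {"type": "integer"},
        "watertight": {"type": "boolean"},
        "surfaceArea": {"type": "number"},
        "enclosedVolume": {"type": "number"},
        "file": {"type": "string"}
      }
    }
  }
}
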