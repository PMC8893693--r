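{
  "description": "Synthetic sagittal-plane muscle path fixture: approximate attachment coordinates chosen for anatomically correct joint crossings, sign conventions and plausible moment-arm magnitudes. NOT measured from any subject or taken from a published musculoskeletal model; analyses based on these paths are qualitative (signs/trends). Frames: origin at the segment's proximal chain joint (foot: toe pivot O; shank: ankle; thigh: knee; pelvis/hat: hip); local +x along the segment toward its distal joint (pelvis: superior at neutral tilt); +y = +x rotated 90 deg CCW (posterior for an upright right limb). Units: meters.",
  "muscles": [
    {
      "name": "glut_max",
      "group": "gluteus_maximus",
      "comment": "sacral origin, sacrotuberous wrap-approximation via point on the posterior-inferior pelvis, insertion at the gluteal tuberosity; hip extensor. Placement gives an extension moment arm declining from about 7.5 cm near hip extension to about 2.5 cm in deep flexion, the behavior of via-point gluteal paths in standard gait models.",
      "points": [
        {"frame": "pelvis", "x": 0.060, "y": 0.090},
        {"frame": "pelvis", "x": -0.045, "y": 0.060},
        {"frame": "thigh", "x": 0.330, "y": 0.045}
      ]
    },
    {
      "name": "biceps_fem_lh",
      "group": "biceps_femoris",
      "comment": "ischial tuberosity (about 7 cm inferior, slightly posterior to the hip centre) to the fibular head just distal-posterior to the knee; hip extensor, knee flexor",
      "points": [
        {"frame": "pelvis", "x": -0.0739, "y": 0.0130},
        {"frame": "shank", "x": 0.375, "y": 0.025}
      ]
    },
    {
      "name": "rect_fem",
      "group": "rectus_femoris",
      "comment": "anterior inferior iliac spine via the patella (distal-anterior to the femoral shaft) to the tibial tuberosity; hip flexor, knee extensor",
      "points": [
        {"frame": "pelvis", "x": 0.0525, "y": -0.0291},
        {"frame": "thigh", "x": -0.045, "y": -0.050},
        {"frame": "shank", "x": 0.345, "y": -0.042}
      ]
    },
    {
      "name": "vasti",
      "group": "vasti",
      "comment": "mid anterior femur via the patella to the tibial tuberosity; knee extensor (lumped vastus group)",
      "points": [
        {"frame": "thigh", "x": 0.220, "y": -0.045},
        {"frame": "thigh", "x": -0.045, "y": -0.050},
        {"frame": "shank", "x": 0.345, "y": -0.042}
      ]
    },
    {
      "name": "gas_med",
      "group": "gastrocnemius",
      "comment": "medial femoral condyle via a retro-malleolar wrap-approximation point to the calcaneus; knee flexor, ankle plantarflexor",
      "points": [
        {"frame": "thigh", "x": 0.025, "y": 0.028},
        {"frame": "foot", "x": -0.045, "y": 0.078},
        {"frame": "foot", "x": -0.050, "y": 0.030}
      ]
    },
    {
      "name": "gas_lat",
      "group": "gastrocnemius",
      "comment": "lateral femoral condyle via a retro-malleolar wrap-approximation point to the calcaneus; knee flexor, ankle plantarflexor",
      "points": [
        {"frame": "thigh", "x": 0.030, "y": 0.033},
        {"frame": "foot", "x": -0.044, "y": 0.076},
        {"frame": "foot", "x": -0.048, "y": 0.030}
      ]
    },
    {
      "name": "soleus",
      "group": "soleus",
      "comment": "proximal posterior tibia via a retro-malleolar wrap-approximation point to the calcaneus; ankle plantarflexor. The via point keeps the Achilles lever arm stable (about 4.5 to 3.4 cm over 0-40 deg dorsiflexion) as a straight shank-to-heel line would not.",
      "points": [
        {"frame": "shank", "x": 0.280, "y": 0.042},
        {"frame": "foot", "x": -0.045, "y": 0.078},
        {"frame": "foot", "x": -0.050, "y": 0.030}
      ]
    },
    {
      "name": "tib_ant",
      "group": "tibialis_anterior",
      "comment": "anterior tibial shaft to the dorsal midfoot; ankle dorsiflexor",
      "points": [
        {"frame": "shank", "x": 0.260, "y": -0.030},
        {"frame": "foot", "x": 0.050, "y": 0.062}
      ]
    }
  ]
}
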