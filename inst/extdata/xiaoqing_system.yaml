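# Multifunctional river indicator system (Xiaoqing River configuration).
# Four criteria (A1-A4), twelve sub-criteria (B1-B12), twenty-two indicators
# (C1-C22), each scored on a five-grade ladder I (excellent) .. V (poor).
# Interval notation: "[a, b)" etc.; "> v" / ">= v" mark unbounded grades;
# a bare number is a single-point grade.  Bidirectional indicators list one
# or two interval branches per grade (best inside a central band).
name: xiaoqing_system
criteria:
  - {id: A1, name: Environmental function, subcriteria: [B1, B2, B3]}
  - {id: A2, name: Ecological function, subcriteria: [B4, B5, B6]}
  - {id: A3, name: Social function, subcriteria: [B7, B8, B9]}
  - {id: A4, name: Economic function, subcriteria: [B10, B11, B12]}
subcriteria:
  - {id: B1, name: Hydrological function, indicators: [C1, C2]}
  - {id: B2, name: Water quality purification function, indicators: [C3, C4, C5]}
  - {id: B3, name: Self-repairing/regulating function, indicators: [C6]}
  - {id: B4, name: Biological habitat function, indicators: [C7, C8, C9]}
  - {id: B5, name: River corridor function, indicators: [C10, C11]}
  - {id: B6, name: Soil and water conservation function, indicators: [C12]}
  - {id: B7, name: Flood control and transportation function, indicators: [C13, C14]}
  - {id: B8, name: Water supply function, indicators: [C15, C16]}
  - {id: B9, name: Recreational function, indicators: [C17]}
  - {id: B10, name: Economic benefit, indicators: [C18, C19]}
  - {id: B11, name: Aquaculture benefit, indicators: [C20]}
  - {id: B12, name: Tourist industry benefit, indicators: [C21, C22]}
indicators:
  - id: C1
    name: Monthly average flow rate of change
    unit: "%"
    direction: negative
    subcriterion: B1
    grades:
      I: "[0, 0.2]"
      II: "(0.2, 0.4]"
      III: "(0.4, 0.6]"
      IV: "(0.6, 0.8]"
      V: "> 0.8"
  - id: C2
    name: Degree of ecological flow satisfaction
    unit: "%"
    direction: positive
    subcriterion: B1
    grades:
      I: "[98, 100]"
      II: "[90, 98)"
      III: "[80, 90)"
      IV: "[60, 80)"
      V: "[0, 60)"
  - id: C3
    name: Rate of drinking water source water quality standards
    unit: "%"
    direction: positive
    subcriterion: B2
    grades:
      I: "[90, 100]"
      II: "[80, 90)"
      III: "[70, 80)"
      IV: "[60, 70)"
      V: "[0, 60)"
  - id: C4
    name: Surface water quality
    unit: "-"
    direction: categorical
    subcriterion: B2
    grades:
      I: "5"
      II: "4"
      III: "3"
      IV: "2"
      V: "1"
  - id: C5
    name: Substrate contamination index
    unit: "-"
    direction: negative
    subcriterion: B2
    grades:
      I: "[0, 1)"
      II: "[1, 2)"
      III: "[2, 3)"
      IV: "[3, 5)"
      V: ">= 5"
  - id: C6
    name: Self-purification capacity of water bodies
    unit: "mg/L"
    direction: positive
    subcriterion: B3
    grades:
      I: "> 7.5"
      II: "(5, 7.5]"
      III: "(3, 5]"
      IV: "(2, 3]"
      V: "[0, 2]"
  - id: C7
    name: Phytoplankton diversity index
    unit: "-"
    direction: positive
    subcriterion: B4
    grades:
      I: "> 3"
      II: "(2, 3]"
      III: "(1, 2]"
      IV: "(0, 1]"
      V: "0"
  - id: C8
    name: Zooplankton diversity index
    unit: "-"
    direction: positive
    subcriterion: B4
    grades:
      I: "> 3"
      II: "(2, 3]"
      III: "(1, 2]"
      IV: "(0, 1]"
      V: "0"
  - id: C9
    name: Benthic macroinvertebrate diversity index
    unit: "-"
    direction: positive
    subcriterion: B4
    grades:
      I: "> 3"
      II: "(2, 3]"
      III: "(1, 2]"
      IV: "(0, 1]"
      V: "0"
  - id: C10
    name: River vertical connection index
    unit: "pcs/100 km"
    direction: negative
    subcriterion: B5
    grades:
      I: "[0, 0.3)"
      II: "[0.3, 0.5)"
      III: "[0.5, 0.8)"
      IV: "[0.8, 1.2)"
      V: ">= 1.2"
  - id: C11
    name: Landscape fragmentation
    unit: "%"
    direction: negative
    subcriterion: B5
    grades:
      I: "[0, 30]"
      II: "(30, 60]"
      III: "(60, 80]"
      IV: "(80, 90]"
      V: "(90, 100]"
  - id: C12
    name: Suspended sand transportation modulus
    unit: "t/km2"
    direction: negative
    subcriterion: B6
    grades:
      I: "[0, 50]"
      II: "(50, 100]"
      III: "(100, 200]"
      IV: "(200, 500]"
      V: "> 500"
  - id: C13
    name: Attainment rate of flood control engineering measures
    unit: "%"
    direction: positive
    subcriterion: B7
    grades:
      I: "[95, 100]"
      II: "[85, 95)"
      III: "[70, 85)"
      IV: "[50, 70)"
      V: "[0, 50)"
  - id: C14
    name: Percentage of navigable river sections
    unit: "%"
    direction: positive
    subcriterion: B7
    grades:
      I: "[90, 100]"
      II: "[80, 90)"
      III: "[60, 80)"
      IV: "[30, 60)"
      V: "[0, 30)"
  - id: C15
    name: Modulus of groundwater resources
    unit: "million m3/km2"
    direction: positive
    subcriterion: B8
    grades:
      I: "> 50"
      II: "(30, 50]"
      III: "(20, 30]"
      IV: "(10, 20]"
      V: "[0, 10]"
  - id: C16
    name: Utilization rate of water resources
    unit: "%"
    direction: bidirectional
    subcriterion: B8
    grades:
      I: ["[25, 30]"]
      II: ["[20, 25)", "(30, 40]"]
      III: ["[10, 20)", "(40, 50]"]
      IV: ["[5, 10)", "(50, 60]"]
      V: ["[0, 5)", "(60, 100]"]
  - id: C17
    name: Degree of human activity demand satisfaction
    unit: "%"
    direction: positive
    subcriterion: B9
    grades:
      I: "[90, 100]"
      II: "[80, 90)"
      III: "[60, 80)"
      IV: "[30, 60)"
      V: "[0, 30)"
  - id: C18
    name: Per capita GDP
    unit: "million"
    direction: positive
    subcriterion: B10
    grades:
      I: "> 15"
      II: "(12, 15]"
      III: "(10, 12]"
      IV: "(5, 10]"
      V: "[0, 5]"
  - id: C19
    name: Water consumption of 10,000 CNY GDP
    unit: "m3"
    direction: negative
    subcriterion: B10
    grades:
      I: "[0, 15)"
      II: "[15, 25)"
      III: "[25, 45)"
      IV: "[45, 80)"
      V: ">= 80"
  - id: C20
    name: Fish production capacity
    unit: "-"
    direction: positive
    subcriterion: B11
    grades:
      I: "[90, 100]"
      II: "[80, 90)"
      III: "[60, 80)"
      IV: "[30, 60)"
      V: "[0, 30)"
  - id: C21
    name: Average tourist flow index
    unit: "-"
    direction: positive
    subcriterion: B12
    grades:
      I: "> 3"
      II: "(2, 3]"
      III: "(1, 2]"
      IV: "(0, 1]"
      V: "0"
  - id: C22
    name: Visibility of scenic area
    unit: "%"
    direction: positive
    subcriterion: B12
    grades:
      I: "[90, 100]"
      II: "[80, 90)"
      III: "[60, 80)"
      IV: "[30, 60)"
      V: "[0, 30)"
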