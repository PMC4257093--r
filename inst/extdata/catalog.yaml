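# Respiratory reductase catalog.
#
# Each entry: name, oxygen category (aerobic | microaerobic | anaerobic |
# none), substrate, mode (respiratory | assimilatory | transport), optional
# nitrogen-oxide pathway_step (NO3_to_NO2, NO2_to_NH3, NO2_to_NO, NO_to_N2O,
# N2O_to_N2, transporter), and subunits with roles (catalytic,
# membrane_anchor, electron_transfer, maturation) matched by domain-family
# accession. Catalytic subunits of the molybdopterin oxidoreductase
# superfamily carry a subunit-specific accession here; the proteins
# themselves additionally carry the shared PF00384 family used for
# family-level enumeration. Entries with category `none` (assimilatory
# enzymes, transporters) never affect oxygen classification.
reductases:
  # ---- aerobic terminal oxidases (catalytic subunits share PF00115) ----
  - name: Cyo
    category: aerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: FAM_CYOB}
      - {role: electron_transfer, family: FAM_CYOA}
      - {role: membrane_anchor, family: FAM_CYOC}
  - name: Qox
    category: aerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: FAM_QOXB}
      - {role: membrane_anchor, family: FAM_QOXC}
  - name: Cta
    category: aerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: FAM_CTAD}
      - {role: electron_transfer, family: FAM_CTAC}
  - name: Cco
    category: aerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: FAM_CCON}
      - {role: electron_transfer, family: FAM_CCOO}
  # ---- microaerobic (high oxygen affinity) ----
  - name: Cyd
    category: microaerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: FAM_CYDA}
      - {role: membrane_anchor, family: FAM_CYDB}
  - name: Cyf
    category: microaerobic
    substrate: oxygen
    subunits:
      - {role: catalytic, family: PF00578}     # AhpC/TSA oxygen/thiol binding
      - {role: membrane_anchor, family: PF01077} # membrane FeS electron transfer
      - {role: electron_transfer, family: FAM_CYFF} # extracellular flavin binding
  # ---- anaerobic reductases ----
  - name: Frd
    category: anaerobic
    substrate: fumarate
    subunits:
      - {role: catalytic, family: FAM_FRDA}
      - {role: electron_transfer, family: FAM_FRDB}
      - {role: membrane_anchor, family: FAM_FRDC}
  - name: Nar
    category: anaerobic
    substrate: nitrate
    pathway_step: NO3_to_NO2
    subunits:
      - {role: catalytic, family: FAM_NARG}
      - {role: electron_transfer, family: FAM_NARH}
      - {role: membrane_anchor, family: FAM_NARI}
  - name: Nap
    category: anaerobic
    substrate: nitrate
    pathway_step: NO3_to_NO2
    subunits:
      - {role: catalytic, family: FAM_NAPA}
      - {role: electron_transfer, family: FAM_NAPB}
  - name: Nrf
    category: anaerobic
    substrate: nitrite
    pathway_step: NO2_to_NH3
    subunits:
      - {role: catalytic, family: FAM_NRFA}
      - {role: electron_transfer, family: FAM_NRFB}
      - {role: electron_transfer, family: PF13247} # 4Fe-4S (NrfC-like)
      - {role: membrane_anchor, family: PF03916}   # NrfD/TtrC integral membrane
  - name: NirK
    category: anaerobic
    substrate: nitrite
    pathway_step: NO2_to_NO
    subunits:
      - {role: catalytic, family: FAM_NIRK}
  - name: Nor
    category: anaerobic
    substrate: nitric oxide
    pathway_step: NO_to_N2O
    subunits:
      - {role: catalytic, family: FAM_NORB}
      - {role: electron_transfer, family: FAM_NORC}
  - name: Nos
    category: anaerobic
    substrate: nitrous oxide
    pathway_step: N2O_to_N2
    subunits:
      - {role: catalytic, family: FAM_NOSZ}
      - {role: maturation, family: FAM_NOSD}
      - {role: maturation, family: FAM_NOSL}
      - {role: maturation, family: FAM_NOSF}
      - {role: membrane_anchor, family: FAM_NOSY}
  - name: Dms
    category: anaerobic
    substrate: DMSO/TMAO
    subunits:
      - {role: catalytic, family: FAM_DMSA}
      - {role: electron_transfer, family: PF13247}
      - {role: membrane_anchor, family: FAM_DMSC}
  - name: Tor
    category: anaerobic
    substrate: TMAO
    subunits:
      - {role: catalytic, family: FAM_TORA}
      - {role: electron_transfer, family: FAM_TORB}
      - {role: membrane_anchor, family: FAM_TORC}
      - {role: maturation, family: FAM_TORD}
  - name: Ttr
    category: anaerobic
    substrate: tetrathionate
    subunits:
      - {role: catalytic, family: FAM_TTRA}
      - {role: electron_transfer, family: PF13247}
      - {role: membrane_anchor, family: PF03916}
  - name: Phs
    category: anaerobic
    substrate: thiosulfate
    subunits:
      - {role: catalytic, family: FAM_PHSA}
      - {role: electron_transfer, family: FAM_PHSB}
      - {role: membrane_anchor, family: FAM_PHSC}
  - name: Tsr
    category: anaerobic
    substrate: thiosulfate
    subunits:
      - {role: catalytic, family: FAM_CYTC552}   # c-552/4-like cytochrome
      - {role: maturation, family: FAM_NRFG}
      - {role: electron_transfer, family: PF13247}
      - {role: membrane_anchor, family: PF03916}
      - {role: maturation, family: FAM_NOSD}
      - {role: maturation, family: FAM_NOSL}
  - name: Ynf
    category: anaerobic
    substrate: selenate
    subunits:
      - {role: catalytic, family: FAM_YNFE}
      - {role: membrane_anchor, family: FAM_YNFH}
  - name: Asr
    category: anaerobic
    substrate: sulfite
    subunits:
      - {role: catalytic, family: FAM_ASRA}
      - {role: electron_transfer, family: FAM_ASRB}
      - {role: membrane_anchor, family: FAM_ASRC}
  - name: Apr
    category: anaerobic
    substrate: adenylyl sulfate
    subunits:
      - {role: catalytic, family: FAM_APRA}
      - {role: electron_transfer, family: FAM_APRB}
  - name: Hdr
    category: anaerobic
    substrate: heterodisulfide
    subunits:
      - {role: catalytic, family: FAM_HDRA}
      - {role: electron_transfer, family: FAM_HDRB}
  - name: Arr
    category: anaerobic
    substrate: arsenate
    subunits:
      - {role: catalytic, family: FAM_ARRA}
      - {role: electron_transfer, family: FAM_ARRB}
  # ---- assimilatory enzymes and transporters (no oxygen category) ----
  - name: NirBD
    category: none
    mode: assimilatory
    substrate: nitrite
    pathway_step: NO2_to_NH3
    subunits:
      - {role: catalytic, family: FAM_NIRB}
      - {role: electron_transfer, family: FAM_NIRD}
  - name: NasBA
    category: none
    mode: assimilatory
    substrate: nitrate
    pathway_step: NO3_to_NO2
    subunits:
      - {role: catalytic, family: FAM_NASA}
      - {role: electron_transfer, family: FAM_NASB}
  - name: NarK
    category: none
    mode: transport
    substrate: nitrate/nitrite
    pathway_step: transporter
    subunits:
      - {role: catalytic, family: FAM_NARK}
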