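<?xml version="1.0" encoding="UTF-8"?>
<!-- SYNTHETIC fixture: shaped like a ligands-by-UniProt RESTful response
     (accession P21802, fibroblast growth factor receptor 2); structures
     and affinities are invented for offline testing. -->
<bdb:getLigandsByUniprotResponse xmlns:bdb="http://example.org/bdb">
  <bdb:affinities>
    <bdb:monomerid>50000001</bdb:monomerid>
    <bdb:smiles>CC(=O)Nc1ccc(O)cc1</bdb:smiles>
    <bdb:affinity_type>Ki</bdb:affinity_type>
    <bdb:affinity>120</bdb:affinity>
  </bdb:affinities>
  <bdb:affinities>
    <bdb:monomerid>50000002</bdb:monomerid>
    <bdb:smiles>CCOC(=O)c1ccccc1N</bdb:smiles>
    <bdb:affinity_type>IC50</bdb:affinity_type>
    <bdb:affinity>3500</bdb:affinity>
  </bdb:affinities>
  <bdb:affinities>
    <bdb:monomerid>50000003</bdb:monomerid>
    <bdb:smiles>c1ccc2[nH]ccc2c1</bdb:smiles>
    <bdb:affinity_type>IC50</bdb:affinity_type>
    <bdb:affinity>&gt;10000</bdb:affinity>
  </bdb:affinities>
  <bdb:affinities>
    <bdb:monomerid>50000004</bdb:monomerid>
    <bdb:smiles>CN1CCN(CC1)c1ccccc1</bdb:smiles>
    <bdb:affinity_type>Ki</bdb:affinity_type>
    <bdb:affinity>55000</bdb:affinity>
  </bdb:affinities>
</bdb:getLigandsByUniprotResponse>
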