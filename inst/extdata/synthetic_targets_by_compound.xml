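<?xml version="1.0" encoding="UTF-8"?>
<!-- SYNTHETIC fixture: shaped like a targets-by-compound RESTful
     response for an exact-structure search (similarity = 1) with a
     flavonoid query known to inhibit enoyl-acyl-carrier protein
     reductase; affinities are transcribed test values, other records
     invented. -->
<bdb:getTargetByCompoundResponse xmlns:bdb="http://example.org/bdb">
  <bdb:affinities>
    <bdb:monomerid>60000001</bdb:monomerid>
    <bdb:smiles>Oc1cc(O)c2c(c1)oc(-c1cc(O)c(O)c(O)c1)c(O)c2=O</bdb:smiles>
    <bdb:target>Enoyl-acyl-carrier protein reductase</bdb:target>
    <bdb:uniprot>Q9BZL1</bdb:uniprot>
    <bdb:affinity_type>IC50</bdb:affinity_type>
    <bdb:affinity>400</bdb:affinity>
    <bdb:similarity>1</bdb:similarity>
  </bdb:affinities>
  <bdb:affinities>
    <bdb:monomerid>60000001</bdb:monomerid>
    <bdb:smiles>Oc1cc(O)c2c(c1)oc(-c1cc(O)c(O)c(O)c1)c(O)c2=O</bdb:smiles>
    <bdb:target>HIV-1 integrase</bdb:target>
    <bdb:uniprot>P12497</bdb:uniprot>
    <bdb:affinity_type>IC50</bdb:affinity_type>
    <bdb:affinity>890</bdb:affinity>
    <bdb:similarity>1</bdb:similarity>
  </bdb:affinities>
  <bdb:affinities>
    <bdb:monomerid>60000001</bdb:monomerid>
    <bdb:smiles>Oc1cc(O)c2c(c1)oc(-c1cc(O)c(O)c(O)c1)c(O)c2=O</bdb:smiles>
    <bdb:target>Serine/threonine-protein kinase PIM1</bdb:target>
    <bdb:uniprot>P11309</bdb:uniprot>
    <bdb:affinity_type>Ki</bdb:affinity_type>
    <bdb:affinity>640</bdb:affinity>
    <bdb:similarity>1</bdb:similarity>
  </bdb:affinities>
</bdb:getTargetByCompoundResponse>
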