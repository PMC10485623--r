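# Four-cell segment polarity network, Albert-Othmer Boolean formulation,
# re-encoded in dominant-inhibition + frozen-clause form.
# Cells 0..3 form a ring; per-cell rules are identical; inter-cell
# membrane contacts are symmetric. Non-dominant-inhibition logic is
# carried as frozen clauses: SMO (activation by absence of PTC), PTC
# (self-persistence removed by neighboring HH), ci (constitutive
# transcription). PRESPEC lines mark the prior-knowledge interactions:
# the five gene->protein activations, the three wg-rule composites, PTC
# self-persistence, and the SMO frozen-clause companions (11 per-cell
# templates).
SPECIES wg gene
SPECIES en gene
SPECIES hh gene
SPECIES ptc gene
SPECIES ci gene
SPECIES SLP internal_protein
SPECIES EN internal_protein
SPECIES CI internal_protein
SPECIES CIR internal_protein
SPECIES CIA internal_protein
SPECIES WG membrane_protein
SPECIES PTC membrane_protein
SPECIES SMO membrane_protein
SPECIES PH membrane_protein
SPECIES HH membrane_protein
SPECIES wg@1 gene
SPECIES en@1 gene
SPECIES hh@1 gene
SPECIES ptc@1 gene
SPECIES ci@1 gene
SPECIES SLP@1 internal_protein
SPECIES EN@1 internal_protein
SPECIES CI@1 internal_protein
SPECIES CIR@1 internal_protein
SPECIES CIA@1 internal_protein
SPECIES WG@1 membrane_protein
SPECIES PTC@1 membrane_protein
SPECIES SMO@1 membrane_protein
SPECIES PH@1 membrane_protein
SPECIES HH@1 membrane_protein
SPECIES wg@2 gene
SPECIES en@2 gene
SPECIES hh@2 gene
SPECIES ptc@2 gene
SPECIES ci@2 gene
SPECIES SLP@2 internal_protein
SPECIES EN@2 internal_protein
SPECIES CI@2 internal_protein
SPECIES CIR@2 internal_protein
SPECIES CIA@2 internal_protein
SPECIES WG@2 membrane_protein
SPECIES PTC@2 membrane_protein
SPECIES SMO@2 membrane_protein
SPECIES PH@2 membrane_protein
SPECIES HH@2 membrane_protein
SPECIES wg@3 gene
SPECIES en@3 gene
SPECIES hh@3 gene
SPECIES ptc@3 gene
SPECIES ci@3 gene
SPECIES SLP@3 internal_protein
SPECIES EN@3 internal_protein
SPECIES CI@3 internal_protein
SPECIES CIR@3 internal_protein
SPECIES CIA@3 internal_protein
SPECIES WG@3 membrane_protein
SPECIES PTC@3 membrane_protein
SPECIES SMO@3 membrane_protein
SPECIES PH@3 membrane_protein
SPECIES HH@3 membrane_protein
RULE wg <- ACT( (CIA & SLP) ; (CIA & wg) ; (SLP & wg) ) INH( CIR )
RULE en <- ACT( WG@1 ; WG@3 ) INH( SLP )
RULE hh <- ACT( EN ) INH( CIR )
RULE ptc <- ACT( CIA ) INH( CIR ; EN )
RULE ci <- ACT( ) INH( EN ) FROZEN: TRUE
RULE EN <- ACT( en ) INH( )
RULE CI <- ACT( ci ) INH( )
RULE CIR <- ACT( CI ) INH( hh@1 ; hh@3 ; SMO )
RULE CIA <- ACT( (CI & hh@1) ; (CI & hh@3) ; (CI & SMO) ) INH( )
RULE WG <- ACT( wg ) INH( )
RULE PTC <- ACT( ptc ) INH( ) FROZEN: !HH@1 & !HH@3 & PTC
RULE SMO <- ACT( ) INH( ) FROZEN: !PTC | HH@1 | HH@3
RULE PH <- ACT( (HH@1 & PTC) ; (HH@3 & PTC) ) INH( )
RULE HH <- ACT( hh ) INH( )
RULE wg@1 <- ACT( (CIA@1 & SLP@1) ; (CIA@1 & wg@1) ; (SLP@1 & wg@1) ) INH( CIR@1 )
RULE en@1 <- ACT( WG ; WG@2 ) INH( SLP@1 )
RULE hh@1 <- ACT( EN@1 ) INH( CIR@1 )
RULE ptc@1 <- ACT( CIA@1 ) INH( CIR@1 ; EN@1 )
RULE ci@1 <- ACT( ) INH( EN@1 ) FROZEN: TRUE
RULE EN@1 <- ACT( en@1 ) INH( )
RULE CI@1 <- ACT( ci@1 ) INH( )
RULE CIR@1 <- ACT( CI@1 ) INH( hh ; hh@2 ; SMO@1 )
RULE CIA@1 <- ACT( (CI@1 & hh) ; (CI@1 & hh@2) ; (CI@1 & SMO@1) ) INH( )
RULE WG@1 <- ACT( wg@1 ) INH( )
RULE PTC@1 <- ACT( ptc@1 ) INH( ) FROZEN: !HH & !HH@2 & PTC@1
RULE SMO@1 <- ACT( ) INH( ) FROZEN: !PTC@1 | HH | HH@2
RULE PH@1 <- ACT( (HH@2 & PTC@1) ; (HH & PTC@1) ) INH( )
RULE HH@1 <- ACT( hh@1 ) INH( )
RULE wg@2 <- ACT( (CIA@2 & SLP@2) ; (CIA@2 & wg@2) ; (SLP@2 & wg@2) ) INH( CIR@2 )
RULE en@2 <- ACT( WG@1 ; WG@3 ) INH( SLP@2 )
RULE hh@2 <- ACT( EN@2 ) INH( CIR@2 )
RULE ptc@2 <- ACT( CIA@2 ) INH( CIR@2 ; EN@2 )
RULE ci@2 <- ACT( ) INH( EN@2 ) FROZEN: TRUE
RULE EN@2 <- ACT( en@2 ) INH( )
RULE CI@2 <- ACT( ci@2 ) INH( )
RULE CIR@2 <- ACT( CI@2 ) INH( hh@1 ; hh@3 ; SMO@2 )
RULE CIA@2 <- ACT( (CI@2 & hh@1) ; (CI@2 & hh@3) ; (CI@2 & SMO@2) ) INH( )
RULE WG@2 <- ACT( wg@2 ) INH( )
RULE PTC@2 <- ACT( ptc@2 ) INH( ) FROZEN: !HH@1 & !HH@3 & PTC@2
RULE SMO@2 <- ACT( ) INH( ) FROZEN: !PTC@2 | HH@1 | HH@3
RULE PH@2 <- ACT( (HH@1 & PTC@2) ; (HH@3 & PTC@2) ) INH( )
RULE HH@2 <- ACT( hh@2 ) INH( )
RULE wg@3 <- ACT( (CIA@3 & SLP@3) ; (CIA@3 & wg@3) ; (SLP@3 & wg@3) ) INH( CIR@3 )
RULE en@3 <- ACT( WG ; WG@2 ) INH( SLP@3 )
RULE hh@3 <- ACT( EN@3 ) INH( CIR@3 )
RULE ptc@3 <- ACT( CIA@3 ) INH( CIR@3 ; EN@3 )
RULE ci@3 <- ACT( ) INH( EN@3 ) FROZEN: TRUE
RULE EN@3 <- ACT( en@3 ) INH( )
RULE CI@3 <- ACT( ci@3 ) INH( )
RULE CIR@3 <- ACT( CI@3 ) INH( hh ; hh@2 ; SMO@3 )
RULE CIA@3 <- ACT( (CI@3 & hh) ; (CI@3 & hh@2) ; (CI@3 & SMO@3) ) INH( )
RULE WG@3 <- ACT( wg@3 ) INH( )
RULE PTC@3 <- ACT( ptc@3 ) INH( ) FROZEN: !HH & !HH@2 & PTC@3
RULE SMO@3 <- ACT( ) INH( ) FROZEN: !PTC@3 | HH | HH@2
RULE PH@3 <- ACT( (HH@2 & PTC@3) ; (HH & PTC@3) ) INH( )
RULE HH@3 <- ACT( hh@3 ) INH( )
PRESPEC ci -> CI +
PRESPEC ci@1 -> CI@1 +
PRESPEC ci@2 -> CI@2 +
PRESPEC ci@3 -> CI@3 +
PRESPEC CIA@1&SLP@1 -> wg@1 +
PRESPEC CIA@1&wg@1 -> wg@1 +
PRESPEC CIA@2&SLP@2 -> wg@2 +
PRESPEC CIA@2&wg@2 -> wg@2 +
PRESPEC CIA@3&SLP@3 -> wg@3 +
PRESPEC CIA@3&wg@3 -> wg@3 +
PRESPEC CIA&SLP -> wg +
PRESPEC CIA&wg -> wg +
PRESPEC en -> EN +
PRESPEC en@1 -> EN@1 +
PRESPEC en@2 -> EN@2 +
PRESPEC en@3 -> EN@3 +
PRESPEC hh -> HH +
PRESPEC HH -> SMO@1 +
PRESPEC HH -> SMO@3 +
PRESPEC hh@1 -> HH@1 +
PRESPEC HH@1 -> SMO +
PRESPEC HH@1 -> SMO@2 +
PRESPEC hh@2 -> HH@2 +
PRESPEC HH@2 -> SMO@1 +
PRESPEC HH@2 -> SMO@3 +
PRESPEC hh@3 -> HH@3 +
PRESPEC HH@3 -> SMO +
PRESPEC HH@3 -> SMO@2 +
PRESPEC ptc -> PTC +
PRESPEC PTC -> PTC +
PRESPEC PTC -> SMO -
PRESPEC ptc@1 -> PTC@1 +
PRESPEC PTC@1 -> PTC@1 +
PRESPEC PTC@1 -> SMO@1 -
PRESPEC ptc@2 -> PTC@2 +
PRESPEC PTC@2 -> PTC@2 +
PRESPEC PTC@2 -> SMO@2 -
PRESPEC ptc@3 -> PTC@3 +
PRESPEC PTC@3 -> PTC@3 +
PRESPEC PTC@3 -> SMO@3 -
PRESPEC SLP@1&wg@1 -> wg@1 +
PRESPEC SLP@2&wg@2 -> wg@2 +
PRESPEC SLP@3&wg@3 -> wg@3 +
PRESPEC SLP&wg -> wg +
PRESPEC wg -> WG +
PRESPEC wg@1 -> WG@1 +
PRESPEC wg@2 -> WG@2 +
PRESPEC wg@3 -> WG@3 +
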