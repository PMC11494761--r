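{
  "genes": [
    {
      "symbol": "TNNT2",
      "contig": "chr1",
      "start": 1000,
      "end": 1379,
      "description": "cardiomyopathy panel gene TNNT2",
      "transcripts": [
        {
          "id": "TNNT2_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 1020,
          "cds_end": 1301,
          "exons": [
            {
              "start": 1000,
              "end": 1139
            },
            {
              "start": 1200,
              "end": 1379
            }
          ]
        }
      ]
    },
    {
      "symbol": "CAPZA1",
      "contig": "chr1",
      "start": 2000,
      "end": 2379,
      "description": "cardiomyopathy panel gene CAPZA1",
      "transcripts": [
        {
          "id": "CAPZA1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 2020,
          "cds_end": 2301,
          "exons": [
            {
              "start": 2000,
              "end": 2139
            },
            {
              "start": 2200,
              "end": 2379
            }
          ]
        }
      ]
    },
    {
      "symbol": "MYL1",
      "contig": "chr2",
      "start": 3000,
      "end": 3379,
      "description": "cardiomyopathy panel gene MYL1",
      "transcripts": [
        {
          "id": "MYL1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 3020,
          "cds_end": 3301,
          "exons": [
            {
              "start": 3000,
              "end": 3139
            },
            {
              "start": 3200,
              "end": 3379
            }
          ]
        }
      ]
    },
    {
      "symbol": "DES",
      "contig": "chr2",
      "start": 4000,
      "end": 4379,
      "description": "cardiomyopathy panel gene DES",
      "transcripts": [
        {
          "id": "DES_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 4020,
          "cds_end": 4301,
          "exons": [
            {
              "start": 4000,
              "end": 4139
            },
            {
              "start": 4200,
              "end": 4379
            }
          ]
        }
      ]
    },
    {
      "symbol": "TTN",
      "contig": "chr2",
      "start": 5000,
      "end": 5379,
      "description": "cardiomyopathy panel gene TTN",
      "transcripts": [
        {
          "id": "TTN_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 5020,
          "cds_end": 5301,
          "exons": [
            {
              "start": 5000,
              "end": 5139
            },
            {
              "start": 5200,
              "end": 5379
            }
          ]
        }
      ]
    },
    {
      "symbol": "TNNC1",
      "contig": "chr3",
      "start": 6000,
      "end": 6379,
      "description": "cardiomyopathy panel gene TNNC1",
      "transcripts": [
        {
          "id": "TNNC1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 6020,
          "cds_end": 6301,
          "exons": [
            {
              "start": 6000,
              "end": 6139
            },
            {
              "start": 6200,
              "end": 6379
            }
          ]
        }
      ]
    },
    {
      "symbol": "MYBPC3",
      "contig": "chr11",
      "start": 7000,
      "end": 7379,
      "description": "cardiomyopathy panel gene MYBPC3",
      "transcripts": [
        {
          "id": "MYBPC3_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 7020,
          "cds_end": 7301,
          "exons": [
            {
              "start": 7000,
              "end": 7139
            },
            {
              "start": 7200,
              "end": 7379
            }
          ]
        }
      ]
    },
    {
      "symbol": "MYL2",
      "contig": "chr12",
      "start": 8000,
      "end": 8379,
      "description": "cardiomyopathy panel gene MYL2",
      "transcripts": [
        {
          "id": "MYL2_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 8020,
          "cds_end": 8301,
          "exons": [
            {
              "start": 8000,
              "end": 8139
            },
            {
              "start": 8200,
              "end": 8379
            }
          ]
        }
      ]
    },
    {
      "symbol": "ACTN1",
      "contig": "chr14",
      "start": 9000,
      "end": 9379,
      "description": "cardiomyopathy panel gene ACTN1",
      "transcripts": [
        {
          "id": "ACTN1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 9020,
          "cds_end": 9301,
          "exons": [
            {
              "start": 9000,
              "end": 9139
            },
            {
              "start": 9200,
              "end": 9379
            }
          ]
        }
      ]
    },
    {
      "symbol": "MYH7",
      "contig": "chr14",
      "start": 10000,
      "end": 10379,
      "description": "cardiomyopathy panel gene MYH7",
      "transcripts": [
        {
          "id": "MYH7_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 10020,
          "cds_end": 10301,
          "exons": [
            {
              "start": 10000,
              "end": 10139
            },
            {
              "start": 10200,
              "end": 10379
            }
          ]
        }
      ]
    },
    {
      "symbol": "MYH6",
      "contig": "chr14",
      "start": 11000,
      "end": 11379,
      "description": "cardiomyopathy panel gene MYH6",
      "transcripts": [
        {
          "id": "MYH6_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 11020,
          "cds_end": 11301,
          "exons": [
            {
              "start": 11000,
              "end": 11139
            },
            {
              "start": 11200,
              "end": 11379
            }
          ]
        }
      ]
    },
    {
      "symbol": "TPM1",
      "contig": "chr15",
      "start": 12000,
      "end": 12379,
      "description": "cardiomyopathy panel gene TPM1",
      "transcripts": [
        {
          "id": "TPM1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 12020,
          "cds_end": 12301,
          "exons": [
            {
              "start": 12000,
              "end": 12139
            },
            {
              "start": 12200,
              "end": 12379
            }
          ]
        }
      ]
    },
    {
      "symbol": "ACTC1",
      "contig": "chr15",
      "start": 13000,
      "end": 13379,
      "description": "cardiomyopathy panel gene ACTC1",
      "transcripts": [
        {
          "id": "ACTC1_T1",
          "strand": "+",
          "canonical": true,
          "cds_start": 13020,
          "cds_end": 13301,
          "exons": [
            {
              "start": 13000,
              "end": 13139
            },
            {
              "start": 13200,
              "end": 13379
            }
          ]
        }
      ]
    }
  ]
}
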